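# seqcurator

Curating a public sequencing dataset is mostly unglamorous, error-prone
work: collecting run-level metadata from an archive, downloading dozens
of FASTQ files, convincing yourself that the files on disk are the files
the metadata promises, consolidating multiple sequencing runs into one
file per biological sample, and — when several studies are combined into
a meta-analysis — making sure the final tables agree with a common
schema. `seqcurator` is an R package that turns this process into a
scriptable workflow of small programs with uniform, severity-coded
reports.

The package is centred on the run/sample model of the European
Nucleotide Archive (ENA): one *study* holds many *runs* (each with one
or two FASTQ files, for SINGLE or PAIRED layouts), and each run derives
from a *sample*. Most tools also work in a generic mode driven by a
manifest (file-to-sample) table, so non-ENA datasets can be curated the
same way.

## The workflow

| Step | Function(s) | CLI subcommand |
| --- | --- | --- |
| Fetch study metadata | `fetch_ena_metadata()` | `download-metadata-ena` |
| Download FASTQ files | `plan_fastq_urls()`, `download_urls()` | `download-fastqs` |
| Screen run-level metadata | `check_metadata_ena()` | `check-metadata-ena` |
| Screen the download directory | `check_fastqs()` | `check-fastqs` |
| Merge extra metadata | `merge_metadata()` | `merge-metadata` |
| Filter rows sequentially | `filter_metadata()` | `filter-metadata` |
| Plan per-sample consolidation | `make_treatment_template()` | `make-treatment-template` |
| Execute the plan on files | `treat_fastqs()` | `treat-fastqs` |
| Consolidate metadata per sample | `treat_metadata()` | `treat-metadata` |
| Validate against a dictionary | `check_metadata_values()` | `check-metadata-values` |
| Concatenate datasets | `concat_datasets()` | `concat-datasets` |

Every check emits `finding` objects with a fixed code and severity
(`info` < `warning` < `error`; see `finding_registry()`), bundled into a
`curation_report` that prints as text and serializes as a findings TSV.
Exit codes are 0/1/2 by worst severity, so shell pipelines can branch on
the outcome.

A deterministic synthetic-dataset generator (`generate_dataset()`) and a
defect injector (`inject_defect()`, mapping documented in
`defect_check_map()`) emulate ENA-style studies — metadata, manifests,
dictionaries and gzipped FASTQ files with true MD5 digests — so the
whole workflow is testable offline.

## Worked example

```r
library(seqcurator)

dir <- tempfile(); ds <- generate_dataset(fixture_config(seed = 7, n_samples = 4), dir)
ds
#> <synthetic dataset: 6 run(s), 8 fastq file(s) in /tmp/.../fix1>

report <- check_metadata_ena(ds$metadata)
findings_table(report$findings)
#>   severity                code subjects
#> 1     info RUN_SAMPLE_RELATION
#>                                                      message
#> 1 6 run(s) over 4 sample(s): 1.50 runs per sample on average

check_fastqs(ds$metadata, file.path(dir, "fastqs"), md5 = TRUE)$status
#> [1] "info"
```

Six runs over four samples, every expected file present with a matching
MD5 digest: all three checks come back with informational findings
only, which is the generator's contract for defect-free data. Deleting
a file, corrupting one byte, or editing a digest flips exactly one
documented finding code to `warning`/`error` (try
`inject_defect(ds, "CORRUPT_FILE")`).

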