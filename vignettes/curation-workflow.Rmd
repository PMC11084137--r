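---
title: "Curating public sequencing datasets with seqcurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating public sequencing datasets with seqcurator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcurator)
```

## The problem

Public sequencing archives hold an enormous amount of reusable data,
but a study pulled from the European Nucleotide Archive (ENA) or a
mirrored INSDC database rarely arrives analysis-ready. Metadata is
scattered between the archive's run-level table and the publication's
supplementary files; the FASTQ files of one biological sample are split
across several sequencing runs; download errors and silent corruption
happen; and when several studies are combined into a meta-analysis,
each arrives with its own column names, value conventions and
duplicated identifiers. `seqcurator` structures this curation into a
workflow of small programs — collection, control checks, optional
treatment, and integration — each consuming and producing plain
tab-separated tables so that every intermediate state is inspectable
and archivable.

This vignette explains the model behind each stage, the conventions and
tunable parameters, the design choices made where several behaviours
were defensible, and what the synthetic test data does and does not
demonstrate.

## Data model and file conventions

The central artifact is the **run-level metadata table**: one row per
sequencing run. In the *ena* dialect the columns follow the ENA Portal
API filereport field names (`run_accession`, `sample_accession`,
`library_layout`, `fastq_ftp`, `fastq_md5`, organism, platform and
data-type fields, `submitted_ftp`); a *generic* dialect accepts any
columns. Cells that describe several files of one run (URLs, digests)
hold one value per file separated by `";"` — the archive's own
convention, exposed via `split_multivalue()`.

On disk every table is UTF-8, tab-separated, one header row, Unix
newlines, no quoting. Missing cells are written as the empty string;
on reading, the tokens `""`, `NA`, `na`, `NaN`, `nan` and `None` all
parse to missing. This token set is deliberately permissive because
public tables mix conventions; the cost is that a cell whose *literal*
text is one of these tokens cannot round-trip, which we accept as the
lesser evil. Everything else round-trips byte-for-byte, and the test
suite asserts write-then-read identity on random tables.

Every check program returns a `curation_report`: an ordered list of
findings plus summary tallies. A **finding** has a code from a single
fixed registry (`finding_registry()`), a severity bound to that code
(`info` < `warning` < `error`), the affected subjects and a message.
Severities encode a policy: *error* means curation cannot proceed
safely, *warning* means a human should look, *info* is descriptive.
Reports render deterministically, and programs exit 0/1/2 by worst
severity so the workflow is scriptable.

## Collection

`fetch_ena_metadata()` separates the *what* from the *where*: it takes
a fetcher object with two functions — a run-level filereport and
long-format per-sample attribute records — and joins the attributes
onto run rows by sample accession. The live `ena_portal_fetcher()` is
one implementation; `fixture_fetcher()` replays recorded TSV responses,
which is what all tests use. When an attribute name collides with a
filereport column the attribute is stored under `<name>_attr` and a
warning is emitted: silently overwriting archive columns would destroy
provenance.

`download_urls()` fetches each URL to its basename under the
destination directory, never aborts the batch on a transport error,
retries each URL (default 2 re-attempts), and writes the failed URLs to
`download_errors.txt` — a file whose format is exactly the input
format, so relaunching failures is `download_urls(read_url_list(...))`.
Defaults are deliberately polite toward public mirrors: parallelism 4,
sequential when 1. MD5 digests are *not* verified at download time;
integrity is the check programs' job, keeping collection and control
check separated. Two distinct URLs sharing a basename fail with
`NAME_COLLISION` rather than silently overwriting each other.

## Control checks

`check_metadata_ena()` computes the descriptive statistics a curator
scans first (runs, samples, tallies of organism, platform, layout and
data type, and the grouping of samples by run count) and three families
of checks:

* **Layout versus file count.** SINGLE expects exactly 1 `fastq_ftp`
  entry and PAIRED exactly 2. PAIRED with 3 files is reported only at
  info level (`PAIRED_WITH_ORPHAN`) because the archive convention
  allows an extra unpaired-reads file; every other combination warns.
* **Submitted files.** Runs without original uploads are noted;
  duplicated submitted basenames across runs are warned, since they
  break basename-keyed reconciliation downstream.
* **Per-sample consistency.** Multiple sample-identity columns are
  compared as partitions of the runs (two rows equal in one column but
  split by another is a disagreement), and each sample is checked for
  multiple distinct values of organism, platform, layout and data
  type. Missing cells never count as a conflicting value, so one real
  organism plus missing cells is not a conflict. The organism,
  platform and data-type families are checked component-wise (either
  member of the pair having two values triggers the family's single
  finding per sample).

`check_fastqs()` reconciles a download directory with the expectation:
expected-but-absent basenames are errors, present-but-unlisted fastqs
warnings, and a basename claimed by more than one row a warning
(matching is by basename because archive-generated names are globally
unique; datasets with colliding generic names surface as
`FILE_MULTIMATCH`). MD5 verification is opt-in (`md5 = TRUE`) because
it dominates runtime on large datasets; digests are computed over the
raw (compressed) bytes with `tools::md5sum()`, which streams at C level
and therefore needs constant memory regardless of file size. In
generic mode a manifest drives the reconciliation and the
manifest/metadata file and sample sets are compared for divergences.

## Optional treatment

`merge_metadata()` implements the four standard relational joins with a
left join as the default (the archive table is the reference, the
publication's table the annex). Keys are compared by exact string
equality after trimming surrounding whitespace — no case folding, so
curators are never surprised by silent identifier mangling. The unique
key values present in only one source are always reported; an extra key
matching several rows fans out and is flagged `KEY_MULTIMATCH`.

`filter_metadata()` applies an ordered list of steps, each keeping or
dropping categorical values or applying a numeric comparison
(integers and `"."`-decimals only; no locale handling). Every step
carries its own `na_policy`, because "keep the unknowns" and "drop the
unknowns" are both legitimate and the choice must be explicit and
archivable. Steps live in a TSV control file so the filter provenance
travels with the dataset. The per-step report satisfies
`rows_before - rows_removed = rows_after` chained across steps, which
the tests assert against brute-force predicate evaluation.

The three treatment programs turn raw run files into canonical
per-sample files named `<sample>_1.fastq.gz` / `<sample>_2.fastq.gz`
(paired) or `<sample>.fastq.gz` (single):

* `make_treatment_template()` proposes a plan — `copy` when the file is
  already canonical, `rename` when only the name differs, `merge` per
  read side when a sample has several runs, inputs ordered by run
  accession. Read sides are inferred from the `_1`/`_2`, `_R1`/`_R2`
  and `.1`/`.2` suffixes; anything ambiguous (mixed layouts within a
  sample, unrecognizable sides) is left blank for the curator, and
  unclaimed files get a blank-sample row plus a warning. The template
  is a TSV meant to be reviewed and edited before execution.
* `treat_fastqs()` validates the template first (unknown inputs,
  duplicate inputs or outputs, arity violations, blank fields) and
  refuses to run otherwise. Merging is raw gzip-member concatenation:
  concatenated gzip streams are themselves valid gzip, so merges are
  lossless and fast with no recompression. Inputs are never modified;
  outputs are only overwritten on request. A sample mixing PAIRED and
  SINGLE runs is not merged automatically — the template stays blank
  there because no automatic choice is defensible.
* `treat_metadata()` collapses run rows to one row per sample. Columns
  on which all runs agree keep their value; disagreements are
  `";"`-joined in run order and recorded in a warning report, because a
  conflicting per-sample value is exactly the kind of inconsistency a
  meta-analysis must resolve before use. Run-specific columns
  (accessions, URLs, digests — see `run_specific_columns()`) are joined
  silently since they differ by construction.

## Validation and integration

A **variables dictionary** gives each variable its requiredness, class
(`character`, which also accepts boolean tokens, or `numeric`),
uniqueness, and an allowed-value analysis: `any`, `subset` (observed ⊆
allowed), `wholeset` (set equality — the subset direction *plus*
coverage of every allowed value, which is what distinguishes it from
`subset`), or an inclusive numeric `range` written `min..max`.
Crosschecks between variables are run in both directions and each
direction reports separately, since "one patient ID per sample alias"
and "one alias per patient ID" fail independently. Missing cells never
violate class, uniqueness or allowed-value analyses — missingness is
governed by requiredness alone. `check_variable()` always reports in
the fixed order presence → class → uniqueness → crosscheck → allowed,
so reports from different datasets are comparable.

`concat_datasets()` refuses tables that fail validation with errors
(warnings pass — they are advisory by definition), appends rows under
the dictionary's column order with optional columns missing-filled,
adds a `dataset_origin` column, and re-checks every unique variable
across datasets: the same subject identifier appearing in two studies
is reported as `CROSS_DATASET_DUPLICATE`, the classic silent killer of
pooled analyses. After `treat_metadata()`, `curated_dictionary()`
rewrites a run-level dictionary for the per-sample table (the sample
column becomes unique; run-specific columns relax to free-form, since
they now hold `";"`-joined lists).

## The synthetic data generator

`generate_dataset()` fabricates a study the way the checks expect to
see one: synthetic accessions (`ERR` + 7 digits, `SAMEA` + 8 digits),
per-sample layout and platform, gzipped FASTQ files of well-formed
4-line records whose true digests fill `fastq_md5`, a manifest, and a
dictionary covering every column. Reads are uniform-random ACGT with
constant quality `I`: the package curates *files*, never bases, so
biological realism would add nothing the checks can observe. URLs use
`file://` (or a caller-supplied base), making download tests
self-contained. Generation is deterministic: identical configuration
and seed give byte-identical output, which the tests assert.

Default problem sizes are deliberately desk-scale — a handful of
samples, 1–3 runs each, 25 reads per file — because every property
being tested (set reconciliation, digest mismatches, joins, row
conservation) is size-invariant; the same checks run unchanged on
studies with thousands of runs. What the synthetic data does *not*
emulate: real archives' messier attribute vocabularies, partially
missing columns, nested FTP hierarchies, and transport flakiness
beyond simple unreachable URLs. Passing tests therefore demonstrate
the correctness of the bookkeeping, not robustness to every way a real
archive can surprise you.

`inject_defect()` applies exactly one minimal mutation per defect code
and returns the finding the designated check must now produce
(`defect_check_map()` documents the mapping). Two subtleties are worth
noting. The defect harness uses an all-PAIRED, two-runs-per-sample
configuration so that every defect is structurally applicable whatever
the seed. And `SAMPLE_LAYOUT_CONFLICT` trims the toggled run's file
list along with its layout, so the mutation stays minimal: the
designated check sees the per-sample conflict and nothing else.

## Numerical and degenerate-input choices

* Numeric parsing (filters, dictionary class and range checks) accepts
  integers and `"."`-decimals only; anything else on a non-missing cell
  is an explicit error rather than a silent `NA`.
* Range bounds are inclusive at both ends.
* Empty tables are legal everywhere: a header-only table writes exactly
  one line, summaries report zero runs and samples, and an empty URL
  list downloads nothing and writes no error file.
* Report ordering is fixed by construction (row order, then sorted
  subjects within a finding family), which is what makes repeated runs
  byte-identical.

## Known limitations

File-level curation only: no read-level validation, trimming or
quality control (downstream tools own that), no SRA-archive or
BAM/CRAM input, no FTP resume or mirror hierarchies, no fuzzy key
matching in merges, and no ontology normalization of dictionary
values. The live ENA fetcher constructs Portal API queries but is not
exercised by the offline test suite; the fetcher contract it implements
is tested through recorded fixtures.
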