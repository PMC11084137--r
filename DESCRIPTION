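Package: seqcurator
Title: Curation Workflow for Public Sequencing Dataset Metadata and FASTQ Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow of command-line style programs to collect, check,
    treat and integrate the metadata tables and FASTQ files of public
    sequencing datasets. Centred on the run/sample model of the European
    Nucleotide Archive (ENA) with generic modes for other sources, it
    covers metadata acquisition through a pluggable fetcher, parallel URL
    downloads with error-report relaunch, consistency checks of run-level
    metadata, reconciliation and MD5 verification of downloaded FASTQ
    files, metadata merging and sequential filtering, per-sample
    consolidation of FASTQ files (copy/rename/merge) and of their
    metadata, data-dictionary driven validation, and safe multi-dataset
    concatenation for meta-analyses. A deterministic synthetic-dataset
    generator with a defect injector makes every check testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
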