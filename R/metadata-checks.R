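# Check Metadata ENA: statistics and consistency checks over a run-level
# metadata table, usable at any point of the workflow.

.missing_bucket <- "(missing)"

tally_column <- function(values) {
  v <- as.character(values)
  v[is.na(v)] <- .missing_bucket
  tab <- table(v)
  if (length(tab)) tab[order(names(tab))] else tab
}

#' Summarize runs and samples of a metadata table
#'
#' Computes the descriptive statistics of a run-level table: number of
#' runs, number of distinct samples, frequency tables for organism
#' (scientific name and tax id), sequencing platform (instrument model
#' and platform), library layout, and data type (library strategy and
#' source), plus a grouping of samples by their number of associated
#' runs. Missing cells are counted in a distinct "(missing)" bucket.
#'
#' @param table ENA-dialect metadata data frame.
#' @param sample_column Column holding the sample identity
#'   (default `sample_accession`).
#' @return Object of class `run_sample_summary`: list with `n_runs`,
#'   `n_samples`, `tallies` (named list of frequency tables) and
#'   `runs_per_sample_histogram` (named list: run count -> sorted sample
#'   names).
#' @export
summarize_runs <- function(table, sample_column = "sample_accession") {
  if (!sample_column %in% names(table)) {
    stop("sample column not present: ", sample_column, call. = FALSE)
  }
  fields <- c("scientific_name", "tax_id", "instrument_model",
              "instrument_platform", "library_layout", "library_strategy",
              "library_source")
  fields <- intersect(fields, names(table))
  tallies <- lapply(table[fields], tally_column)
  samples <- table[[sample_column]]
  samples[is.na(samples)] <- .missing_bucket
  runs_per_sample <- table(samples)
  hist <- if (length(runs_per_sample)) {
    lapply(split(names(runs_per_sample), as.integer(runs_per_sample)), sort)
  } else list()
  structure(
    list(n_runs = nrow(table),
         n_samples = length(setdiff(unique(samples), .missing_bucket)),
         tallies = tallies,
         runs_per_sample_histogram = hist),
    class = "run_sample_summary"
  )
}

#' @export
print.run_sample_summary <- function(x, ...) {
  cat(sprintf("%d run(s) over %d sample(s)\n", x$n_runs, x$n_samples))
  for (nm in names(x$tallies)) {
    cat("--", nm, "\n")
    print(x$tallies[[nm]])
  }
  cat("-- samples by number of runs\n")
  for (k in names(x$runs_per_sample_histogram)) {
    cat(sprintf("  %s run(s): %d sample(s)\n", k,
                length(x$runs_per_sample_histogram[[k]])))
  }
  invisible(x)
}

#' Compare library layout with the number of fastq files
#'
#' Per run, the number of ";"-separated `fastq_ftp` entries is compared
#' with the expectation of the declared layout: SINGLE expects exactly 1
#' file, PAIRED exactly 2. A PAIRED run with 3 files is noted at info
#' level (ENA convention allows an extra unpaired-reads file); any other
#' combination is a warning. A missing layout is warned as such.
#'
#' @param table ENA-dialect metadata data frame.
#' @return List of findings (empty when every run conforms).
#' @export
check_layout_vs_fastq_count <- function(table) {
  findings <- list()
  for (i in seq_len(nrow(table))) {
    run <- table$run_accession[i]
    layout <- table$library_layout[i]
    n <- length(split_multivalue(table$fastq_ftp[i]))
    if (is.na(layout)) {
      findings <- c(findings, list(finding(
        "MISSING_LAYOUT", subjects = run,
        message = sprintf("run %s has no library_layout (%d fastq file(s))",
                          run, n))))
    } else if (layout == "SINGLE" && n == 1) {
    } else if (layout == "PAIRED" && n == 2) {
    } else if (layout == "PAIRED" && n == 3) {
      findings <- c(findings, list(finding(
        "PAIRED_WITH_ORPHAN", subjects = run,
        message = sprintf("PAIRED run %s has 3 fastq files (extra unpaired-reads file)",
                          run))))
    } else {
      findings <- c(findings, list(finding(
        "LAYOUT_FILECOUNT_MISMATCH", subjects = run,
        message = sprintf("run %s: layout %s but %d fastq file(s)",
                          run, layout, n))))
    }
  }
  findings
}

#' Check availability and naming of the originally submitted files
#'
#' Reports runs whose `submitted_ftp` cell is empty (the original uploads
#' are unavailable) and file basenames that appear under more than one
#' run — or more than once within one run — in `submitted_ftp`.
#'
#' @param table ENA-dialect metadata data frame.
#' @return List of findings.
#' @export
check_submitted_files <- function(table) {
  findings <- list()
  per_row <- lapply(table$submitted_ftp, split_multivalue)
  empty <- which(lengths(per_row) == 0)
  if (length(empty)) {
    findings <- c(findings, list(finding(
      "SUBMITTED_UNAVAILABLE", subjects = table$run_accession[empty],
      message = sprintf("%d of %d run(s) have no submitted files available",
                        length(empty), nrow(table)))))
  }
  names_by_run <- lapply(per_row, function(u) vapply(u, url_basename, "", USE.NAMES = FALSE))
  all_names <- unlist(names_by_run, use.names = FALSE)
  for (dup in sort(unique(all_names[duplicated(all_names)]))) {
    owners <- table$run_accession[vapply(names_by_run, function(x) dup %in% x, TRUE)]
    findings <- c(findings, list(finding(
      "DUPLICATED_SUBMITTED_NAME", subjects = c(dup, owners),
      message = sprintf("submitted file name %s appears %d times (runs: %s)",
                        dup, sum(all_names == dup),
                        paste(owners, collapse = ", ")))))
  }
  findings
}

# distinct non-missing values of a vector
distinct_values <- function(x) sort(unique(x[!is.na(x)]))

#' Per-sample consistency checks
#'
#' Three families of checks: (a) an informational comparison of the
#' number of runs and samples; (b) for each pair of provided sample
#' columns, whether the two columns group the rows identically (two rows
#' equal in one column but split by the other is a disagreement); (c) for
#' each sample, whether it maps to more than one distinct value of the
#' organism fields (scientific_name, tax_id), the platform fields
#' (instrument_platform, instrument_model), the library layout, or the
#' data-type fields (library_strategy, library_source). Missing cells are
#' never counted as a conflicting value.
#'
#' @param table ENA-dialect metadata data frame.
#' @param sample_columns Character vector of sample-identity columns; the
#'   first is used for the per-sample multi-match checks.
#' @return List of findings.
#' @export
check_sample_consistency <- function(table, sample_columns = "sample_accession") {
  absent <- setdiff(sample_columns, names(table))
  if (length(absent)) {
    stop("sample column(s) not present: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  findings <- list()
  samples <- table[[sample_columns[1]]]
  n_runs <- nrow(table)
  n_samples <- length(distinct_values(samples))
  rel <- if (n_runs == n_samples) "one run per sample" else
    sprintf("%.2f runs per sample on average", n_runs / max(n_samples, 1))
  findings <- c(findings, list(finding(
    "RUN_SAMPLE_RELATION", subjects = character(),
    message = sprintf("%d run(s) over %d sample(s): %s", n_runs, n_samples, rel))))

  # (b) pairwise grouping agreement between sample columns
  if (length(sample_columns) >= 2) {
    pairs <- utils::combn(sample_columns, 2, simplify = FALSE)
    for (p in pairs) {
      a <- table[[p[1]]]; b <- table[[p[2]]]
      keep <- !is.na(a) & !is.na(b)
      a <- a[keep]; b <- b[keep]
      agree <- all(vapply(split(b, a), function(x) length(unique(x)) == 1, TRUE)) &&
        all(vapply(split(a, b), function(x) length(unique(x)) == 1, TRUE))
      if (!agree) {
        findings <- c(findings, list(finding(
          "SAMPLE_COLUMN_DISAGREEMENT", subjects = p,
          message = sprintf("columns %s and %s group the runs differently",
                            p[1], p[2]))))
      }
    }
  }

  # (c) per-sample multi-match on single-valued fields
  field_sets <- list(
    ORGANISM = c("scientific_name", "tax_id"),
    PLATFORM = c("instrument_platform", "instrument_model"),
    LAYOUT   = "library_layout",
    DATATYPE = c("library_strategy", "library_source")
  )
  for (fam in names(field_sets)) {
    cols <- intersect(field_sets[[fam]], names(table))
    if (!length(cols)) next
    for (s in distinct_values(samples)) {
      rows <- which(!is.na(samples) & samples == s)
      for (col in cols) {
        vals <- distinct_values(table[[col]][rows])
        if (length(vals) > 1) {
          findings <- c(findings, list(finding(
            paste0("SAMPLE_MULTIMATCH_", fam), subjects = c(s, vals),
            message = sprintf("sample %s maps to %d values of %s: %s",
                              s, length(vals), col,
                              paste(vals, collapse = ", ")))))
          break # one finding per family per sample
        }
      }
    }
  }
  findings
}

#' Full metadata screening of an ENA-dialect table
#'
#' Composite check: run/sample summary plus the layout, submitted-file
#' and per-sample consistency checks, bundled as one report.
#'
#' @inheritParams check_sample_consistency
#' @return A `curation_report`; its `summaries` hold the frequency tables
#'   of [summarize_runs()].
#' @export
check_metadata_ena <- function(table, sample_columns = "sample_accession") {
  assert_ena_dialect(table)
  smry <- summarize_runs(table, sample_columns[1])
  findings <- c(check_layout_vs_fastq_count(table),
                check_submitted_files(table),
                check_sample_consistency(table, sample_columns))
  summaries <- smry$tallies
  names(summaries) <- paste0("runs by ", names(summaries))
  check_report(findings, summaries)
}
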