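# Check Fastqs: reconcile a download directory against the metadata or a
# manifest table, and verify file integrity with MD5 checksums.

#' Expected fastq basenames of a table
#'
#' For an ENA-dialect table the basenames derive from the ";"-split URL
#' column (`fastq_ftp` by default, `submitted_ftp` on request); for a
#' manifest they are the `fastq_file_name` column. One list element per
#' row.
#'
#' @param expected Metadata or manifest data frame.
#' @param source_column URL column for ENA-dialect tables.
#' @return List (one element per row) of character vectors of basenames.
#' @export
expected_basenames <- function(expected, source_column = "fastq_ftp") {
  if ("fastq_file_name" %in% names(expected)) {
    return(lapply(expected$fastq_file_name,
                  function(x) if (is.na(x)) character() else x))
  }
  if (!source_column %in% names(expected)) {
    stop("column not present: ", source_column, call. = FALSE)
  }
  lapply(expected[[source_column]], function(cell) {
    vapply(split_multivalue(cell), url_basename, "", USE.NAMES = FALSE)
  })
}

row_labels <- function(expected) {
  if ("run_accession" %in% names(expected)) expected$run_accession
  else if ("sample_name" %in% names(expected)) expected$sample_name
  else as.character(seq_len(nrow(expected)))
}

#' Reconcile expected files with a download directory
#'
#' Three finding families: an error MISSING_FILE for every basename the
#' table expects but the directory lacks; a warning UNEXPECTED_FILE for
#' every fastq present on disk but unlisted; a warning FILE_MULTIMATCH
#' for every basename claimed by more than one table row.
#'
#' @param expected Metadata (ENA dialect) or manifest data frame.
#' @param inventory A [directory_inventory()].
#' @param source_column URL column used for ENA-dialect tables.
#' @return List of findings.
#' @export
reconcile_files <- function(expected, inventory, source_column = "fastq_ftp") {
  per_row <- expected_basenames(expected, source_column)
  labels <- row_labels(expected)
  all_expected <- unlist(per_row, use.names = FALSE)
  if (is.null(all_expected)) all_expected <- character()
  findings <- list()
  for (f in sort(setdiff(all_expected, inventory$files))) {
    findings <- c(findings, list(finding(
      "MISSING_FILE", subjects = f,
      message = sprintf("expected file %s is absent from %s",
                        f, inventory$directory))))
  }
  for (f in sort(setdiff(inventory$files, all_expected))) {
    findings <- c(findings, list(finding(
      "UNEXPECTED_FILE", subjects = f,
      message = sprintf("file %s is present but not listed in the table", f))))
  }
  claims <- table(all_expected)
  for (f in sort(names(claims[claims > 1]))) {
    owners <- labels[vapply(per_row, function(x) f %in% x, TRUE)]
    findings <- c(findings, list(finding(
      "FILE_MULTIMATCH", subjects = c(f, owners),
      message = sprintf("file %s is claimed by %d row(s): %s",
                        f, sum(vapply(per_row, function(x) sum(x == f), 0L)),
                        paste(owners, collapse = ", ")))))
  }
  findings
}

#' Expected MD5 digests of a table
#'
#' Pairs the ";"-split URL and digest columns row-wise into a
#' basename -> digest mapping.
#'
#' @param expected Metadata (uses `fastq_ftp`/`fastq_md5`, or the
#'   submitted pair) or manifest (uses `fastq_file_name`/`md5`) data
#'   frame.
#' @param use_submitted Use `submitted_ftp`/`submitted_md5` instead of
#'   the generated fastq columns.
#' @return Named character vector: names are basenames, values digests.
#' @export
expected_md5 <- function(expected, use_submitted = FALSE) {
  if ("fastq_file_name" %in% names(expected)) {
    if (!"md5" %in% names(expected)) return(stats::setNames(character(), character()))
    keep <- !is.na(expected$md5)
    return(stats::setNames(expected$md5[keep], expected$fastq_file_name[keep]))
  }
  url_col <- if (use_submitted) "submitted_ftp" else "fastq_ftp"
  md5_col <- if (use_submitted) "submitted_md5" else "fastq_md5"
  if (!all(c(url_col, md5_col) %in% names(expected))) {
    stop("columns not present: ", url_col, ", ", md5_col, call. = FALSE)
  }
  out <- character()
  for (i in seq_len(nrow(expected))) {
    files <- vapply(split_multivalue(expected[[url_col]][i]), url_basename, "",
                    USE.NAMES = FALSE)
    digests <- split_multivalue(expected[[md5_col]][i])
    n <- min(length(files), length(digests))
    if (n) out[files[seq_len(n)]] <- digests[seq_len(n)]
  }
  out
}

#' Verify MD5 checksums of the files in a directory
#'
#' Computes the MD5 digest of each inventoried file over its raw bytes
#' (so a gzipped fastq is checked as stored, exactly as the archive's
#' digest was computed) and compares it with the expected digest.
#' Inventoried files without an expected digest are noted at info level;
#' basenames expected but absent on disk are skipped here — they are
#' already reported by [reconcile_files()].
#'
#' @param inventory A [directory_inventory()].
#' @param expected_md5 Named character vector basename -> hex digest,
#'   e.g. from [expected_md5()].
#' @return List of findings.
#' @export
verify_md5 <- function(inventory, expected_md5) {
  findings <- list()
  for (f in inventory$files) {
    path <- file.path(inventory$directory, f)
    if (!f %in% names(expected_md5)) {
      findings <- c(findings, list(finding(
        "MD5_UNAVAILABLE", subjects = f,
        message = sprintf("no expected MD5 digest for %s", f))))
      next
    }
    got <- tryCatch(unname(tools::md5sum(path)), error = function(e) NA_character_)
    if (is.na(got)) {
      findings <- c(findings, list(finding(
        "FILE_UNREADABLE", subjects = f,
        message = sprintf("could not read %s to compute its MD5", f))))
      next
    }
    want <- tolower(expected_md5[[f]])
    if (tolower(got) != want) {
      findings <- c(findings, list(finding(
        "MD5_MISMATCH", subjects = f,
        message = sprintf("%s: computed %s but expected %s", f, got, want))))
    }
  }
  findings
}

#' Compare a manifest with a metadata table
#'
#' Reports fastq basenames present in exactly one of the two sources and
#' sample names present in exactly one source.
#'
#' @param manifest Manifest data frame.
#' @param metadata Metadata data frame.
#' @param sample_column Column of `metadata` holding the sample names to
#'   compare with the manifest's `sample_name`.
#' @param source_column URL column of `metadata` providing basenames.
#' @return List of findings.
#' @export
compare_manifest_metadata <- function(manifest, metadata,
                                      sample_column = "sample_accession",
                                      source_column = "fastq_ftp") {
  if (!sample_column %in% names(metadata)) {
    stop("sample column not present in metadata: ", sample_column, call. = FALSE)
  }
  findings <- list()
  man_files <- manifest$fastq_file_name
  meta_files <- unlist(expected_basenames(metadata, source_column), use.names = FALSE)
  for (side in list(c("manifest", "metadata"), c("metadata", "manifest"))) {
    only <- sort(setdiff(
      if (side[1] == "manifest") man_files else meta_files,
      if (side[1] == "manifest") meta_files else man_files))
    if (length(only)) {
      findings <- c(findings, list(finding(
        "MANIFEST_METADATA_DIVERGENCE", subjects = only,
        message = sprintf("%d file(s) only in the %s table: %s",
                          length(only), side[1], paste(only, collapse = ", ")))))
    }
  }
  man_samples <- distinct_values(manifest$sample_name)
  meta_samples <- distinct_values(metadata[[sample_column]])
  only_man <- sort(setdiff(man_samples, meta_samples))
  only_meta <- sort(setdiff(meta_samples, man_samples))
  if (length(only_man)) {
    findings <- c(findings, list(finding(
      "SAMPLE_SET_DIVERGENCE", subjects = only_man,
      message = sprintf("sample(s) only in the manifest: %s",
                        paste(only_man, collapse = ", ")))))
  }
  if (length(only_meta)) {
    findings <- c(findings, list(finding(
      "SAMPLE_SET_DIVERGENCE", subjects = only_meta,
      message = sprintf("sample(s) only in the metadata: %s",
                        paste(only_meta, collapse = ", ")))))
  }
  findings
}

#' Full screening of a download directory
#'
#' Composite check: file reconciliation, optional MD5 verification, and —
#' when a manifest is supplied — the manifest/metadata comparison.
#'
#' @param expected Metadata (ENA dialect) or manifest data frame driving
#'   the expectation. In generic mode pass the manifest here too.
#' @param dir Download directory.
#' @param manifest Optional manifest data frame (generic mode): the
#'   reconciliation then runs against the manifest and the
#'   manifest/metadata comparison is added.
#' @param md5 Verify MD5 digests (opt-in; dominates runtime on large
#'   datasets).
#' @param use_submitted Expect `submitted_ftp` files instead of
#'   `fastq_ftp`.
#' @param sample_column Metadata column compared with the manifest's
#'   sample names in generic mode.
#' @return A `curation_report`.
#' @export
check_fastqs <- function(expected, dir, manifest = NULL, md5 = FALSE,
                         use_submitted = FALSE,
                         sample_column = "sample_accession") {
  inv <- directory_inventory(dir)
  source_column <- if (use_submitted) "submitted_ftp" else "fastq_ftp"
  target <- if (is.null(manifest)) expected else manifest
  findings <- reconcile_files(target, inv, source_column)
  if (md5) {
    digests <- if ("fastq_ftp" %in% names(expected)) {
      expected_md5(expected, use_submitted)
    } else if (!is.null(manifest)) expected_md5(manifest) else
      expected_md5(expected)
    findings <- c(findings, verify_md5(inv, digests))
  }
  if (!is.null(manifest) && "fastq_ftp" %in% names(expected)) {
    findings <- c(findings, compare_manifest_metadata(
      manifest, expected, sample_column = sample_column,
      source_column = source_column))
  }
  summaries <- list(files = data.frame(
    what = c("on disk", "expected"),
    n = c(length(inv$files),
          length(unique(unlist(expected_basenames(target, source_column))))),
    stringsAsFactors = FALSE))
  check_report(findings, summaries)
}
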