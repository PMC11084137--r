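# Make Treatment Template / Treat Fastqs / Treat Metadata: planning and
# executing the copy/rename/merge consolidation of raw fastq files into
# canonical per-sample files, and consolidating their run-level metadata.
#
# Canonical output naming: <sample>_1.fastq.gz / <sample>_2.fastq.gz for
# paired reads, <sample>.fastq.gz for single reads.

.template_columns <- c("sample_name", "operation", "input_files",
                       "read_side", "output_file")

#' Infer the read side from a fastq basename
#'
#' Recognizes the suffixes `_1`/`_2`, `_R1`/`_R2` and `.1`/`.2`
#' immediately before the fastq suffix; anything else is `NA` (left to
#' the curator).
#'
#' @param basename Fastq file basename.
#' @return `"R1"`, `"R2"` or `NA_character_`.
#' @export
infer_read_side <- function(basename) {
  stem <- sub(.fastq_suffix_re, "", basename)
  if (grepl("(_R?1|\\.1)$", stem)) "R1"
  else if (grepl("(_R?2|\\.2)$", stem)) "R2"
  else NA_character_
}

canonical_name <- function(sample, side) {
  switch(side,
         R1 = paste0(sample, "_1.fastq.gz"),
         R2 = paste0(sample, "_2.fastq.gz"),
         single = paste0(sample, ".fastq.gz"))
}

template_row <- function(sample, operation, inputs, side, output) {
  data.frame(sample_name = sample, operation = operation,
             input_files = paste(inputs, collapse = ";"),
             read_side = side, output_file = output,
             stringsAsFactors = FALSE)
}

#' Generate a raw treatment template
#'
#' Plans, for every downloaded fastq file, how it becomes part of a
#' canonical per-sample file: samples with a single run get `copy` rows
#' (or `rename` when the basename is not already canonical); samples
#' with several runs of one layout get one `merge` row per read side,
#' inputs ordered by run accession; ambiguous cases (mixed layouts,
#' unrecognizable read side of a paired file) are left with a blank
#' operation for the curator. Files in the directory that no sample
#' claims get a blank-sample row and a warning.
#'
#' The resulting template is a plan to be reviewed (and possibly edited)
#' before [treat_fastqs()] / [treat_metadata()] execute it.
#'
#' @param expected ENA-dialect metadata or manifest data frame linking
#'   files to samples.
#' @param inventory A [directory_inventory()] of the download directory.
#' @param sample_column Sample-identity column of an ENA-dialect table.
#' @return List with `template` (data frame with columns `sample_name`,
#'   `operation`, `input_files`, `read_side`, `output_file`) and
#'   `findings`.
#' @export
make_treatment_template <- function(expected, inventory,
                                    sample_column = "sample_accession") {
  if (!length(inventory$files)) stop("inventory is empty", call. = FALSE)
  is_manifest <- "fastq_file_name" %in% names(expected)
  per_row <- expected_basenames(expected)
  owners <- data.frame(file = character(), sample = character(),
                       run = character(), layout = character(),
                       stringsAsFactors = FALSE)
  for (i in seq_along(per_row)) {
    files <- per_row[[i]]
    if (!length(files)) next
    owners <- rbind(owners, data.frame(
      file = files,
      sample = if (is_manifest) expected$sample_name[i] else expected[[sample_column]][i],
      run = if (is_manifest) expected$fastq_file_name[i] else expected$run_accession[i],
      layout = if (is_manifest) NA_character_ else expected$library_layout[i],
      stringsAsFactors = FALSE))
  }
  owners <- owners[owners$file %in% inventory$files, , drop = FALSE]

  findings <- list()
  rows <- list()
  orphans <- setdiff(inventory$files, owners$file)
  for (s in unique(owners$sample)) {
    own <- owners[owners$sample == s, , drop = FALSE]
    own <- own[order(own$run, own$file), , drop = FALSE]
    runs <- unique(own$run)
    layouts <- distinct_values(own$layout)
    if (is_manifest) {
      sides <- vapply(own$file, infer_read_side, "", USE.NAMES = FALSE)
      layouts <- if (all(!is.na(sides))) "PAIRED" else if (all(is.na(sides)) &&
                                                          nrow(own) == length(runs)) "SINGLE" else layouts
    }
    if (length(layouts) != 1) {
      # mixed or undeterminable layout: leave for the curator
      for (k in seq_len(nrow(own))) {
        rows[[length(rows) + 1]] <- template_row(s, NA_character_, own$file[k],
                                                 NA_character_, NA_character_)
      }
      next
    }
    layout <- layouts
    if (layout == "SINGLE") {
      if (length(runs) == 1) {
        out <- canonical_name(s, "single")
        op <- if (own$file[1] == out) "copy" else "rename"
        rows[[length(rows) + 1]] <- template_row(s, op, own$file[1], "single", out)
      } else {
        rows[[length(rows) + 1]] <- template_row(s, "merge", own$file, "single",
                                                 canonical_name(s, "single"))
      }
    } else { # PAIRED
      sides <- vapply(own$file, infer_read_side, "", USE.NAMES = FALSE)
      if (anyNA(sides)) {
        for (k in seq_len(nrow(own))) {
          rows[[length(rows) + 1]] <- template_row(s, NA_character_, own$file[k],
                                                   NA_character_, NA_character_)
        }
        next
      }
      for (side in intersect(c("R1", "R2"), sides)) {
        files <- own$file[sides == side]
        out <- canonical_name(s, side)
        if (length(files) == 1) {
          op <- if (files == out) "copy" else "rename"
          rows[[length(rows) + 1]] <- template_row(s, op, files, side, out)
        } else {
          rows[[length(rows) + 1]] <- template_row(s, "merge", files, side, out)
        }
      }
    }
  }
  for (f in orphans) {
    rows[[length(rows) + 1]] <- template_row(NA_character_, NA_character_, f,
                                             NA_character_, NA_character_)
    findings <- c(findings, list(finding(
      "ORPHAN_FILE", subjects = f,
      message = sprintf("file %s has no owning sample in the table", f))))
  }
  template <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(), 0, 5),
                                  stringsAsFactors = FALSE), .template_columns)
  rownames(template) <- NULL
  list(template = template, findings = findings)
}

#' Read / write a treatment template
#'
#' The template is a TSV with exactly the columns `sample_name`,
#' `operation`, `input_files` (";"-separated basenames), `read_side`
#' (`R1`, `R2` or `single`) and `output_file`.
#'
#' @param path File path.
#' @return The template data frame.
#' @export
read_treatment_template <- function(path) {
  tab <- read_metadata_table(path)
  absent <- setdiff(.template_columns, names(tab))
  if (length(absent)) {
    stop("treatment template is missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tab[.template_columns]
}

#' @rdname read_treatment_template
#' @param template Template data frame.
#' @export
write_treatment_template <- function(template, path) {
  write_metadata_table(template[.template_columns], path)
}

#' Validate a treatment template against a directory
#'
#' Precondition gate for the two executors: reports (as error findings)
#' any input basename absent from the directory, inputs used by more than
#' one row, duplicated output files, an input count that contradicts the
#' operation (copy/rename take exactly one input, merge at least two),
#' and blank sample/operation/output fields. The template is executable
#' iff the returned list is empty.
#'
#' @param template Template data frame.
#' @param inventory A [directory_inventory()].
#' @return List of findings (empty iff executable).
#' @export
validate_treatment_template <- function(template, inventory) {
  findings <- list()
  inputs_by_row <- lapply(template$input_files, split_multivalue)
  for (i in seq_len(nrow(template))) {
    lbl <- sprintf("row %d", i)
    op <- template$operation[i]
    inputs <- inputs_by_row[[i]]
    blank <- c(if (is.na(template$sample_name[i])) "sample_name",
               if (is.na(op)) "operation",
               if (is.na(template$output_file[i])) "output_file",
               if (!length(inputs)) "input_files")
    if (length(blank)) {
      findings <- c(findings, list(finding(
        "TEMPLATE_BLANK_FIELD", subjects = lbl,
        message = sprintf("%s has blank field(s): %s", lbl,
                          paste(blank, collapse = ", ")))))
      next
    }
    if (!op %in% c("copy", "rename", "merge")) {
      findings <- c(findings, list(finding(
        "TEMPLATE_BLANK_FIELD", subjects = lbl,
        message = sprintf("%s has unknown operation '%s'", lbl, op))))
      next
    }
    if ((op %in% c("copy", "rename") && length(inputs) != 1) ||
        (op == "merge" && length(inputs) < 2)) {
      findings <- c(findings, list(finding(
        "TEMPLATE_BAD_ARITY", subjects = lbl,
        message = sprintf("%s: operation %s with %d input file(s)",
                          lbl, op, length(inputs)))))
    }
    unknown <- setdiff(inputs, inventory$files)
    for (f in unknown) {
      findings <- c(findings, list(finding(
        "TEMPLATE_UNKNOWN_INPUT", subjects = f,
        message = sprintf("%s references %s, absent from %s",
                          lbl, f, inventory$directory))))
    }
  }
  all_inputs <- unlist(inputs_by_row, use.names = FALSE)
  for (f in sort(unique(all_inputs[duplicated(all_inputs)]))) {
    findings <- c(findings, list(finding(
      "TEMPLATE_DUPLICATE_INPUT", subjects = f,
      message = sprintf("input file %s appears in more than one row", f))))
  }
  outs <- template$output_file[!is.na(template$output_file)]
  for (f in sort(unique(outs[duplicated(outs)]))) {
    findings <- c(findings, list(finding(
      "TEMPLATE_DUPLICATE_OUTPUT", subjects = f,
      message = sprintf("output file %s is produced by more than one row", f))))
  }
  findings
}

# concatenate files byte-wise; gzip members concatenate into a valid
# multi-member gzip stream, so merged fastq.gz files need no recompression
concat_files <- function(inputs, output) {
  out <- file(output, open = "wb")
  on.exit(close(out))
  for (p in inputs) {
    inp <- file(p, open = "rb")
    repeat {
      chunk <- readBin(inp, "raw", n = 1024 * 1024)
      if (!length(chunk)) break
      writeBin(chunk, out)
    }
    close(inp)
  }
  invisible(output)
}

#' Execute a treatment template on fastq files
#'
#' `copy` produces a byte-identical copy under the same basename,
#' `rename` under the planned output name, and `merge` concatenates the
#' gzipped inputs in template order (gzip-member concatenation, itself a
#' valid gzip stream). Inputs are never modified. The template is
#' validated first and execution refuses to start if it is not
#' executable.
#'
#' @param template Template data frame.
#' @param in_dir Directory holding the input files.
#' @param out_dir Output directory (must differ from `in_dir`; created
#'   if absent).
#' @param overwrite Allow overwriting pre-existing output files.
#' @return Data frame report: one row per output with `output_file`,
#'   `operation`, `sample_name`, `inputs`.
#' @export
treat_fastqs <- function(template, in_dir, out_dir, overwrite = FALSE) {
  if (normalizePath(in_dir, mustWork = TRUE) ==
      normalizePath(out_dir, mustWork = FALSE)) {
    stop("out_dir must differ from in_dir", call. = FALSE)
  }
  problems <- validate_treatment_template(template, directory_inventory(in_dir))
  if (length(problems)) {
    stop("treatment template is not executable:\n",
         paste(vapply(problems, format_finding, ""), collapse = "\n"),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  done <- character()
  for (i in seq_len(nrow(template))) {
    inputs <- split_multivalue(template$input_files[i])
    output <- template$output_file[i]
    dest <- file.path(out_dir, output)
    if (file.exists(dest) && !overwrite) {
      stop("output file already exists (use overwrite): ", dest, call. = FALSE)
    }
    ok <- tryCatch({
      switch(template$operation[i],
             copy = ,
             rename = file.copy(file.path(in_dir, inputs), dest,
                                overwrite = TRUE),
             merge = {
               concat_files(file.path(in_dir, inputs), dest)
               TRUE
             })
    }, error = function(e) FALSE)
    if (!isTRUE(ok)) {
      stop("treatment aborted at ", output,
           "; partial outputs present: ", paste(done, collapse = ", "),
           call. = FALSE)
    }
    done <- c(done, output)
  }
  data.frame(output_file = template$output_file,
             operation = template$operation,
             sample_name = template$sample_name,
             inputs = template$input_files,
             stringsAsFactors = FALSE)
}

.default_run_specific <- c("run_accession", "run_alias", "fastq_ftp",
                           "fastq_md5", "fastq_bytes", "submitted_ftp",
                           "submitted_md5")

#' Default run-specific metadata columns
#'
#' Columns that legitimately differ between the runs of one sample and
#' are therefore ";"-aggregated by [treat_metadata()] without a warning.
#'
#' @return Character vector of column names.
#' @export
run_specific_columns <- function() .default_run_specific

#' Consolidate run-level metadata per sample
#'
#' Produces one metadata row per template sample. For every column, if
#' all contributing run rows agree (ignoring missing cells) the value is
#' kept; if they differ, the distinct values are joined with ";" in run
#' order and a warning record (sample, column, values) is emitted to
#' flag a possible metadata inconsistency. Run-specific columns (run
#' accessions, file URLs/checksums, ...) are ";"-joined without warning.
#'
#' @param template Template data frame.
#' @param metadata Metadata data frame (run-level).
#' @param sample_column Column of `metadata` matching the template's
#'   `sample_name`.
#' @param run_specific Columns aggregated silently; see
#'   [run_specific_columns()].
#' @return List with `table` (per-sample metadata), `report` (data frame
#'   sample/column/values of the conflicts) and `findings`.
#' @export
treat_metadata <- function(template, metadata,
                           sample_column = "sample_accession",
                           run_specific = run_specific_columns()) {
  if (!sample_column %in% names(metadata)) {
    stop("sample column not present: ", sample_column, call. = FALSE)
  }
  samples <- unique(template$sample_name[!is.na(template$sample_name)])
  findings <- list()
  conflicts <- list()
  out_rows <- list()
  order_col <- if ("run_accession" %in% names(metadata)) "run_accession" else sample_column
  for (s in samples) {
    rows <- which(!is.na(metadata[[sample_column]]) & metadata[[sample_column]] == s)
    if (!length(rows)) {
      findings <- c(findings, list(finding(
        "TEMPLATE_SAMPLE_UNMATCHED", subjects = s,
        message = sprintf("template sample %s is absent from the metadata", s))))
      next
    }
    rows <- rows[order(metadata[[order_col]][rows])]
    cells <- character(ncol(metadata))
    for (j in seq_along(metadata)) {
      col <- names(metadata)[j]
      vals <- metadata[[j]][rows]
      nn <- vals[!is.na(vals)]
      if (col %in% run_specific) {
        cells[j] <- if (length(nn)) paste(nn, collapse = ";") else NA_character_
      } else {
        u <- unique(nn)
        if (length(u) <= 1) {
          cells[j] <- if (length(u)) u else NA_character_
        } else {
          cells[j] <- paste(nn, collapse = ";")
          conflicts[[length(conflicts) + 1]] <-
            data.frame(sample = s, column = col,
                       values = paste(u, collapse = ";"),
                       stringsAsFactors = FALSE)
          findings <- c(findings, list(finding(
            "SAMPLE_VALUE_CONFLICT", subjects = c(s, col),
            message = sprintf("sample %s has %d values of %s: %s",
                              s, length(u), col, paste(u, collapse = ", ")))))
        }
      }
    }
    out_rows[[length(out_rows) + 1]] <- cells
  }
  mat <- if (length(out_rows)) do.call(rbind, out_rows) else
    matrix(character(), 0, ncol(metadata))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- names(metadata)
  rownames(out) <- NULL
  report <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(sample = character(), column = character(),
               values = character(), stringsAsFactors = FALSE)
  list(table = out, report = report, findings = findings)
}
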