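# Metadata table I/O. The on-disk contract is deliberately rigid so that
# tables round-trip cell-for-cell: UTF-8, tab-separated, header row, Unix
# newlines, no quoting; missing cells are written as the empty string and
# the tokens "", NA, na, NaN, nan, None parse to missing.

.na_tokens <- c("", "NA", "na", "NaN", "nan", "None")

.ena_required_columns <- c(
  "run_accession", "sample_accession", "library_layout", "fastq_ftp",
  "fastq_md5", "scientific_name", "tax_id", "instrument_platform",
  "instrument_model", "library_strategy", "library_source", "submitted_ftp"
)

#' Required columns of the ENA dialect
#'
#' Column names follow the ENA Portal API filereport field names.
#'
#' @return Character vector of column names.
#' @export
ena_required_columns <- function() .ena_required_columns

#' Read a metadata table
#'
#' Reads a tab-separated table with a header row into a character data
#' frame. Cells equal to one of the missing-value tokens become `NA`.
#' With `dialect = "ena"` the ENA filereport columns are required and the
#' run/sample invariants are enforced.
#'
#' @param path Path to a TSV file.
#' @param dialect `"generic"` (any columns) or `"ena"` (ENA filereport
#'   dialect, see [ena_required_columns()]).
#' @return A character data frame; all columns are character, missing
#'   cells are `NA`. The dialect is recorded in attribute `"dialect"`.
#' @export
read_metadata_table <- function(path, dialect = c("generic", "ena")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty file (no header line): ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicated column names in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(header))) stop("empty column name in header", call. = FALSE)
  body <- lines[-1]
  cells <- lapply(strsplit(body, "\t", fixed = TRUE), function(x) {
    # strsplit drops trailing empty fields; pad back to full width
    length(x) <- length(header)
    x
  })
  tab <- as.data.frame(do.call(rbind, c(cells, list(matrix(character(), 0, length(header))))),
                       stringsAsFactors = FALSE)
  if (!nrow(tab)) tab <- as.data.frame(matrix(character(), 0, length(header)),
                                       stringsAsFactors = FALSE)
  names(tab) <- header
  for (j in seq_along(tab)) {
    col <- as.character(tab[[j]])
    col[is.na(col) | col %in% .na_tokens] <- NA_character_
    tab[[j]] <- col
  }
  if (dialect == "ena") assert_ena_dialect(tab)
  attr(tab, "dialect") <- dialect
  tab
}

#' Check that a table satisfies the ENA dialect
#'
#' @param table A metadata data frame.
#' @return The table, invisibly; stops with an informative error when a
#'   required column is missing, run accessions are missing/duplicated, or
#'   a library layout is neither PAIRED nor SINGLE.
#' @export
assert_ena_dialect <- function(table) {
  absent <- setdiff(.ena_required_columns, names(table))
  if (length(absent)) {
    stop("not an ENA-dialect table; missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  runs <- table[["run_accession"]]
  if (anyNA(runs)) stop("missing run_accession values", call. = FALSE)
  if (anyDuplicated(runs)) {
    stop("duplicated run_accession values: ",
         paste(unique(runs[duplicated(runs)]), collapse = ", "), call. = FALSE)
  }
  lay <- table[["library_layout"]]
  bad <- !is.na(lay) & !lay %in% c("PAIRED", "SINGLE")
  if (any(bad)) {
    stop("library_layout must be PAIRED or SINGLE; found: ",
         paste(unique(lay[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Write a metadata table
#'
#' Inverse of [read_metadata_table()]: UTF-8, tab-separated, header row,
#' Unix newlines, no quoting; `NA` cells are written as the empty string.
#' Cells are written verbatim (multi-value ";" cells are not
#' re-interpreted).
#'
#' @param table A data frame (coerced column-wise to character).
#' @param path Output path; the parent directory must exist.
#' @return The path, invisibly.
#' @export
write_metadata_table <- function(table, path) {
  if (!dir.exists(dirname(path))) {
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  }
  mat <- vapply(seq_along(table), function(j) {
    col <- as.character(table[[j]])
    col[is.na(col)] <- ""
    col
  }, character(nrow(table)))
  if (nrow(table) == 0) mat <- matrix(character(), 0, length(table))
  if (nrow(table) == 1) mat <- matrix(mat, nrow = 1)
  lines <- c(paste(names(table), collapse = "\t"),
             apply(mat, 1, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Split a multi-value cell
#'
#' ENA filereport cells that describe several files of one run
#' (`fastq_ftp`, `fastq_md5`, `submitted_ftp`, `submitted_md5`) hold one
#' value per file separated by ";". A missing or empty cell has zero
#' values. Values keep their content verbatim apart from surrounding
#' whitespace.
#'
#' @param cell Character scalar (may be `NA`).
#' @return Character vector of values (possibly empty).
#' @export
#' @examples
#' split_multivalue("a_1.fastq.gz;a_2.fastq.gz")
split_multivalue <- function(cell) {
  if (length(cell) != 1) stop("split_multivalue() expects a single cell")
  if (is.na(cell) || !nzchar(cell)) return(character())
  trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
}

#' Read a manifest table
#'
#' Generic mapping of fastq file names to sample names for non-ENA
#' datasets; a TSV with columns `fastq_file_name`, `sample_name` and an
#' optional `md5`.
#'
#' @param path Path to the manifest TSV.
#' @return A character data frame with the manifest columns.
#' @export
read_manifest_table <- function(path) {
  tab <- read_metadata_table(path, dialect = "generic")
  need <- c("fastq_file_name", "sample_name")
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stop("manifest is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$fastq_file_name)) {
    stop("duplicated fastq_file_name values in manifest", call. = FALSE)
  }
  if (anyNA(tab$sample_name)) {
    stop("missing sample_name values in manifest", call. = FALSE)
  }
  tab
}

# basename of a URL or path, query strings stripped
url_basename <- function(url) {
  basename(sub("[?#].*$", "", url))
}

# fastq file suffixes recognized on disk
.fastq_suffix_re <- "\\.(fastq|fq)(\\.gz)?$"

#' Inventory the fastq files of a directory
#'
#' @param dir Directory to scan (not recursive).
#' @return Object of class `directory_inventory`: list with `directory`
#'   and `files`, the lexicographically sorted unique basenames ending in
#'   .fastq.gz, .fq.gz, .fastq or .fq.
#' @export
directory_inventory <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- sort(unique(grep(.fastq_suffix_re, list.files(dir), value = TRUE)))
  structure(list(directory = dir, files = files),
            class = "directory_inventory")
}

#' @export
print.directory_inventory <- function(x, ...) {
  cat(sprintf("<directory inventory: %d fastq file(s) in %s>\n",
              length(x$files), x$directory))
  invisible(x)
}
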