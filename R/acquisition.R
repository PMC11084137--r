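# Collection programs: study metadata acquisition through a pluggable
# fetcher, and batch file download with per-URL retry and an error-report
# relaunch loop.

.accession_re <- "^(PRJ[EDN][A-Z][0-9]+|[ESD]RP[0-9]+)$"

#' Is this a valid study accession?
#'
#' Accepts INSDC project/study accessions: PRJEB/PRJNA/PRJDB numbers and
#' ERP/SRP/DRP numbers.
#'
#' @param accession Character scalar.
#' @return Logical.
#' @export
is_study_accession <- function(accession) {
  is.character(accession) && length(accession) == 1 &&
    grepl(.accession_re, accession)
}

#' Metadata fetcher backed by local fixture files
#'
#' A fetcher is a list with two functions, `filereport(accession)`
#' returning a run-level character data frame and
#' `sample_attributes(accession)` returning a long-format data frame with
#' columns `sample_accession`, `attribute`, `value`. This constructor
#' builds one from two TSV files, which is how recorded responses are
#' replayed in tests and offline workflows.
#'
#' @param filereport_path TSV with the run-level filereport.
#' @param attributes_path Optional TSV with the long-format sample
#'   attributes; `NULL` for none.
#' @return A fetcher list usable with [fetch_ena_metadata()].
#' @export
fixture_fetcher <- function(filereport_path, attributes_path = NULL) {
  list(
    filereport = function(accession) read_metadata_table(filereport_path),
    sample_attributes = function(accession) {
      if (is.null(attributes_path)) {
        return(data.frame(sample_accession = character(),
                          attribute = character(), value = character(),
                          stringsAsFactors = FALSE))
      }
      read_metadata_table(attributes_path)
    }
  )
}

#' Live metadata fetcher for the ENA Portal API
#'
#' Builds a fetcher that queries the ENA Portal API filereport endpoint
#' over HTTPS. Requires network access; all tests use [fixture_fetcher()]
#' instead. Sample attributes are not served by the filereport endpoint,
#' so the live fetcher returns an empty attribute set unless a custom
#' attribute source is supplied.
#'
#' @param base_url Portal API base URL.
#' @param fields Filereport fields to request.
#' @return A fetcher list usable with [fetch_ena_metadata()].
#' @export
ena_portal_fetcher <- function(base_url = "https://www.ebi.ac.uk/ena/portal/api",
                               fields = ena_required_columns()) {
  list(
    filereport = function(accession) {
      url <- sprintf(
        "%s/filereport?accession=%s&result=read_run&fields=%s&format=tsv",
        base_url, accession, paste(fields, collapse = ","))
      tmp <- tempfile(fileext = ".tsv")
      on.exit(unlink(tmp))
      utils::download.file(url, tmp, quiet = TRUE, mode = "wb")
      read_metadata_table(tmp)
    },
    sample_attributes = function(accession) {
      data.frame(sample_accession = character(), attribute = character(),
                 value = character(), stringsAsFactors = FALSE)
    }
  )
}

#' Fetch the metadata of an ENA study
#'
#' Obtains the run-level filereport and the per-sample attribute records
#' from the fetcher and joins the attributes onto the run rows by sample
#' accession; each attribute name becomes an additional column. Attribute
#' names that collide with filereport columns are suffixed `_attr` and a
#' warning finding is emitted rather than overwriting provenance.
#'
#' @param study_accession Study accession (PRJ*/ERP/SRP/DRP).
#' @param fetcher A fetcher list, e.g. from [fixture_fetcher()] or
#'   [ena_portal_fetcher()].
#' @return List with `table` (ena-dialect metadata data frame) and
#'   `findings`.
#' @export
fetch_ena_metadata <- function(study_accession, fetcher) {
  if (!is_study_accession(study_accession)) {
    stop("not a valid study accession: ", study_accession, call. = FALSE)
  }
  report <- tryCatch(fetcher$filereport(study_accession),
                     error = function(e) {
                       stop("metadata fetch failed for ", study_accession,
                            ": ", conditionMessage(e), call. = FALSE)
                     })
  if (!nrow(report)) {
    stop("no runs found for study ", study_accession, call. = FALSE)
  }
  assert_ena_dialect(report)
  attrs <- fetcher$sample_attributes(study_accession)
  findings <- list()
  if (nrow(attrs)) {
    need <- c("sample_accession", "attribute", "value")
    if (!all(need %in% names(attrs))) {
      stop("sample attribute records need columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    for (att in unique(attrs$attribute)) {
      colname <- att
      if (att %in% names(report)) {
        colname <- paste0(att, "_attr")
        findings <- c(findings, list(finding(
          "ATTRIBUTE_COLUMN_COLLISION", subjects = att,
          message = sprintf(
            "sample attribute '%s' collides with a filereport column; stored as '%s'",
            att, colname))))
      }
      sub <- attrs[attrs$attribute == att, , drop = FALSE]
      # last record wins if the fetcher repeats an attribute for a sample
      report[[colname]] <-
        sub$value[match(report$sample_accession, sub$sample_accession)]
    }
  }
  attr(report, "dialect") <- "ena"
  list(table = report, findings = findings)
}

#' Plan the fastq URL list of a metadata table
#'
#' Concatenates, in row order, the ";"-split URLs of the chosen source
#' column. Runs with a missing cell contribute no URLs and are reported
#' with a warning; duplicated URLs are retained and reported at info
#' level.
#'
#' @param table ENA-dialect metadata data frame.
#' @param source_column `"fastq_ftp"` (default) or `"submitted_ftp"`.
#' @return List with `urls` (character vector) and `findings`.
#' @export
plan_fastq_urls <- function(table, source_column = c("fastq_ftp", "submitted_ftp")) {
  source_column <- match.arg(source_column)
  if (!source_column %in% names(table)) {
    stop("column not present: ", source_column, call. = FALSE)
  }
  findings <- list()
  per_row <- lapply(table[[source_column]], split_multivalue)
  empty <- which(lengths(per_row) == 0)
  if (length(empty)) {
    runs <- if ("run_accession" %in% names(table)) {
      table$run_accession[empty]
    } else as.character(empty)
    findings <- c(findings, list(finding(
      "MISSING_FASTQ_URL", subjects = runs,
      message = sprintf("%d run(s) have no URL in %s",
                        length(empty), source_column))))
  }
  urls <- unlist(per_row, use.names = FALSE)
  if (is.null(urls)) urls <- character()
  dup <- unique(urls[duplicated(urls)])
  if (length(dup)) {
    findings <- c(findings, list(finding(
      "DUPLICATE_URL", subjects = dup,
      message = sprintf("%d URL(s) appear more than once", length(dup)))))
  }
  list(urls = urls, findings = findings)
}

#' Read / write a URL list file
#'
#' One absolute URL per line; blank lines are rejected on read.
#'
#' @param path File path.
#' @return Character vector of URLs.
#' @export
read_url_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  urls <- readLines(path, warn = FALSE)
  urls <- urls[seq_len(max(which(nzchar(urls)), 0))] # tolerate trailing newline
  if (any(!nzchar(trimws(urls)))) {
    stop("blank entry in URL list: ", path, call. = FALSE)
  }
  trimws(urls)
}

#' @rdname read_url_list
#' @param urls Character vector of URLs.
#' @export
write_url_list <- function(urls, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(urls, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

download_one <- function(url, destfile, retries) {
  for (attempt in seq_len(retries + 1)) {
    ok <- tryCatch({
      status <- suppressWarnings(
        utils::download.file(url, destfile, quiet = TRUE, mode = "wb"))
      status == 0 && file.exists(destfile)
    }, error = function(e) FALSE)
    if (ok) return(list(outcome = "ok", detail = sprintf("attempt %d", attempt)))
    if (file.exists(destfile)) unlink(destfile)
  }
  list(outcome = "failed",
       detail = sprintf("failed after %d attempt(s)", retries + 1))
}

#' Download a list of URLs
#'
#' Fetches every URL into `dest` under its basename. Transport errors are
#' captured per URL and never abort the batch; each URL is retried up to
#' `retries` times. When any URL fails, the failed URLs are written to
#' `<dest>/download_errors.txt`, one per line, so the file can be fed back
#' to this function to relaunch only the failures. Two distinct URLs that
#' share a basename are both failed with code NAME_COLLISION instead of
#' silently overwriting each other.
#'
#' @param urls Character vector of URLs (e.g. from [plan_fastq_urls()] or
#'   [read_url_list()]).
#' @param dest Existing writable destination directory.
#' @param parallelism Number of concurrent downloads (forked; serial
#'   when 1).
#' @param retries Re-attempts per URL after the first try.
#' @return Object of class `download_report`: list with `records` (data
#'   frame url/destination/outcome/detail), `n_ok`, `n_failed`,
#'   `error_file` (path or `NA`).
#' @export
download_urls <- function(urls, dest, parallelism = 4, retries = 2) {
  if (!dir.exists(dest)) stop("destination does not exist: ", dest, call. = FALSE)
  urls <- as.character(urls)
  base <- vapply(urls, url_basename, "", USE.NAMES = FALSE)
  # basename claimed by >1 distinct URL -> the whole group fails
  collide <- vapply(seq_along(urls), function(i) {
    length(unique(urls[base == base[i]])) > 1
  }, TRUE)
  todo <- which(!collide & !duplicated(urls))
  results <- vector("list", length(urls))
  fetch <- function(i) download_one(urls[i], file.path(dest, base[i]), retries)
  if (length(todo)) {
    fetched <- if (parallelism > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(todo, fetch, mc.cores = min(parallelism, length(todo)))
    } else {
      lapply(todo, fetch)
    }
    results[todo] <- fetched
  }
  for (i in seq_along(urls)) {
    if (collide[i]) {
      results[[i]] <- list(outcome = "failed",
                           detail = paste0("NAME_COLLISION: basename ",
                                           base[i],
                                           " claimed by multiple URLs"))
    } else if (is.null(results[[i]])) {
      # duplicate of an earlier identical URL: share its outcome
      first <- match(urls[i], urls)
      results[[i]] <- results[[first]]
      results[[i]]$detail <- paste0("duplicate of earlier URL; ",
                                    results[[i]]$detail)
    }
  }
  records <- data.frame(
    url = urls,
    destination = base,
    outcome = vapply(results, `[[`, "", "outcome"),
    detail = vapply(results, `[[`, "", "detail"),
    stringsAsFactors = FALSE
  )
  failed <- records$url[records$outcome == "failed"]
  error_file <- NA_character_
  if (length(failed)) {
    error_file <- file.path(dest, "download_errors.txt")
    write_url_list(unique(failed), error_file)
  }
  structure(list(records = records,
                 n_ok = sum(records$outcome == "ok"),
                 n_failed = sum(records$outcome == "failed"),
                 error_file = error_file),
            class = "download_report")
}

#' @export
print.download_report <- function(x, ...) {
  cat(sprintf("<download report: %d ok, %d failed>\n", x$n_ok, x$n_failed))
  if (!is.na(x$error_file)) cat("failed URLs written to", x$error_file, "\n")
  invisible(x)
}
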