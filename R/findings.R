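# Severity-coded findings and check reports, the uniform output of every
# control-check program. Codes live in a single fixed registry; the severity
# of a code can never vary between call sites.

.severity_levels <- c("info", "warning", "error")

.finding_registry <- c(
  # acquisition
  ATTRIBUTE_COLUMN_COLLISION   = "warning",
  MISSING_FASTQ_URL            = "warning",
  DUPLICATE_URL                = "info",
  NAME_COLLISION               = "error",
  # run-level metadata checks
  RUN_SAMPLE_RELATION          = "info",
  LAYOUT_FILECOUNT_MISMATCH    = "warning",
  MISSING_LAYOUT               = "warning",
  PAIRED_WITH_ORPHAN           = "info",
  SUBMITTED_UNAVAILABLE        = "info",
  DUPLICATED_SUBMITTED_NAME    = "warning",
  SAMPLE_COLUMN_DISAGREEMENT   = "warning",
  SAMPLE_MULTIMATCH_ORGANISM   = "warning",
  SAMPLE_MULTIMATCH_PLATFORM   = "warning",
  SAMPLE_MULTIMATCH_LAYOUT     = "warning",
  SAMPLE_MULTIMATCH_DATATYPE   = "warning",
  # fastq directory checks
  MISSING_FILE                 = "error",
  UNEXPECTED_FILE              = "warning",
  FILE_MULTIMATCH              = "warning",
  MD5_MISMATCH                 = "error",
  MD5_UNAVAILABLE              = "info",
  FILE_UNREADABLE              = "error",
  MANIFEST_METADATA_DIVERGENCE = "warning",
  SAMPLE_SET_DIVERGENCE        = "warning",
  # merge / filter
  MERGE_KEYS_ALIGNED           = "info",
  MERGE_MAIN_ONLY_KEYS         = "warning",
  MERGE_EXTRA_ONLY_KEYS        = "warning",
  KEY_MULTIMATCH               = "warning",
  CELL_NOT_NUMERIC             = "error",
  # treatment
  ORPHAN_FILE                  = "warning",
  TEMPLATE_UNKNOWN_INPUT       = "error",
  TEMPLATE_DUPLICATE_INPUT     = "error",
  TEMPLATE_DUPLICATE_OUTPUT    = "error",
  TEMPLATE_BAD_ARITY           = "error",
  TEMPLATE_BLANK_FIELD         = "error",
  TEMPLATE_SAMPLE_UNMATCHED    = "error",
  SAMPLE_VALUE_CONFLICT        = "warning",
  # dictionary validation / concatenation
  VARIABLE_MISSING             = "error",
  VARIABLE_OPTIONAL_ABSENT     = "info",
  VARIABLE_NOT_NUMERIC         = "error",
  VARIABLE_NOT_UNIQUE          = "error",
  VARIABLE_MULTIMATCH          = "warning",
  VALUE_NOT_ALLOWED            = "error",
  VALUE_SET_MISMATCH           = "error",
  VALUE_OUT_OF_RANGE           = "error",
  UNDECLARED_VARIABLE          = "info",
  CROSS_DATASET_DUPLICATE      = "error"
)

#' Registry of finding codes
#'
#' Every finding emitted anywhere in the package carries a code from this
#' registry; the severity of a code is fixed here and nowhere else.
#'
#' @return A data frame with columns `code` and `severity`
#'   (one of `"info"`, `"warning"`, `"error"`).
#' @export
#' @examples
#' head(finding_registry())
finding_registry <- function() {
  data.frame(code = names(.finding_registry),
             severity = unname(.finding_registry),
             stringsAsFactors = FALSE)
}

#' Create a finding
#'
#' A finding is one severity-coded observation about the dataset under
#' check: its code (from [finding_registry()]), the entities it concerns,
#' and a human-readable message.
#'
#' @param code Registered finding code (character scalar).
#' @param subjects Character vector of affected entity identifiers
#'   (run/sample/file/variable names); may be empty.
#' @param message Human-readable description.
#' @return An object of class `curation_finding`.
#' @export
finding <- function(code, subjects = character(), message = "") {
  if (!code %in% names(.finding_registry)) {
    stop("unregistered finding code: ", code, call. = FALSE)
  }
  structure(
    list(severity = unname(.finding_registry[[code]]),
         code = code,
         subjects = as.character(subjects),
         message = as.character(message)[1]),
    class = "curation_finding"
  )
}

#' @export
print.curation_finding <- function(x, ...) {
  cat(format_finding(x), "\n")
  invisible(x)
}

format_finding <- function(f) {
  subj <- if (length(f$subjects)) paste0(" [", paste(f$subjects, collapse = ";"), "]") else ""
  sprintf("%-7s %s%s: %s", toupper(f$severity), f$code, subj, f$message)
}

#' Tabulate a list of findings
#'
#' @param findings List of [finding()] objects.
#' @return Data frame with columns severity, code, subjects (";"-joined),
#'   message; zero rows for an empty list.
#' @export
findings_table <- function(findings) {
  if (!length(findings)) {
    return(data.frame(severity = character(), code = character(),
                      subjects = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    severity = vapply(findings, `[[`, "", "severity"),
    code = vapply(findings, `[[`, "", "code"),
    subjects = vapply(findings, function(f) paste(f$subjects, collapse = ";"), ""),
    message = vapply(findings, `[[`, "", "message"),
    stringsAsFactors = FALSE
  )
}

#' Worst severity in a list of findings
#'
#' @param findings List of findings.
#' @return `"info"`, `"warning"` or `"error"`; `"info"` for an empty list.
#' @export
finding_status <- function(findings) {
  if (!length(findings)) return("info")
  .severity_levels[max(match(vapply(findings, `[[`, "", "severity"),
                             .severity_levels))]
}

#' Count findings of given severities
#'
#' @param findings List of findings.
#' @param severities Severities to count; default warnings and errors.
#' @return Integer count.
#' @export
count_findings <- function(findings, severities = c("warning", "error")) {
  sum(vapply(findings, `[[`, "", "severity") %in% severities)
}

#' Assemble a check report
#'
#' Bundles an ordered list of findings with optional named summary tables;
#' the report status is the worst severity present.
#'
#' @param findings List of [finding()] objects.
#' @param summaries Named list of data frames or tables with descriptive
#'   tallies.
#' @return An object of class `curation_report` with elements `findings`,
#'   `summaries`, `status`.
#' @export
check_report <- function(findings = list(), summaries = list()) {
  structure(
    list(findings = findings, summaries = summaries,
         status = finding_status(findings)),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a report as deterministic plain text
#'
#' The same report always renders to the same character vector, so reports
#' serialized from identical inputs are byte-identical.
#'
#' @param report A `curation_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  out <- character()
  for (nm in names(report$summaries)) {
    s <- report$summaries[[nm]]
    out <- c(out, paste0("== ", nm, " =="))
    if (is.table(s)) s <- as.data.frame(s, stringsAsFactors = FALSE)
    if (is.data.frame(s)) {
      out <- c(out, utils::capture.output(print(s, row.names = FALSE)))
    } else {
      out <- c(out, utils::capture.output(print(s)))
    }
  }
  n <- length(report$findings)
  out <- c(out, sprintf("== findings (%d; status %s) ==", n, report$status))
  out <- c(out, vapply(report$findings, format_finding, ""))
  out
}

#' Write findings to a TSV file
#'
#' The machine-readable serialization of a report: one row per finding with
#' columns severity, code, subjects (";"-joined) and message, in emission
#' order.
#'
#' @param findings List of findings, or a `curation_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_findings <- function(findings, path) {
  if (inherits(findings, "curation_report")) findings <- findings$findings
  write_metadata_table(findings_table(findings), path)
  invisible(path)
}

#' Map a report status to a process exit code
#'
#' info -> 0, warning -> 1, error -> 2, so workflow scripts can branch on
#' the outcome of any check program.
#'
#' @param status A severity string or a `curation_report`.
#' @return Integer exit code.
#' @export
status_exit_code <- function(status) {
  if (inherits(status, "curation_report")) status <- status$status
  match(status, .severity_levels) - 1L
}
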