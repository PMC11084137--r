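# Check Metadata Values and Concat Datasets: validating curated tables
# against a user-authored variables dictionary, and concatenating the
# validated tables of several datasets into one meta-analysis table.

.dictionary_columns <- c("name", "requiredness", "class", "uniqueness",
                         "allowed_analysis", "allowed_values",
                         "crosscheck_variables")
.boolean_tokens <- c("true", "false", "True", "False", "TRUE", "FALSE")

#' Construct a variable specification
#'
#' One row of the variables dictionary: the validation schema of a single
#' metadata variable.
#'
#' @param name Variable (column) name.
#' @param requiredness `"required"` or `"optional"`.
#' @param class `"character"` (strings; boolean tokens accepted) or
#'   `"numeric"`.
#' @param uniqueness `"unique"` or `"nonunique"`.
#' @param allowed_analysis `"any"`, `"subset"`, `"wholeset"` or
#'   `"range"` (range only with class numeric).
#' @param allowed_values Character vector of allowed values
#'   (subset/wholeset) or numeric `c(min, max)` bounds (range); must be
#'   empty for `"any"`.
#' @param crosscheck_variables Variables whose mapping to this one is
#'   checked for multi-matches.
#' @return A `variable_spec` list.
#' @export
variable_spec <- function(name, requiredness = "optional",
                          class = "character", uniqueness = "nonunique",
                          allowed_analysis = "any",
                          allowed_values = character(),
                          crosscheck_variables = character()) {
  stopifnot(requiredness %in% c("required", "optional"),
            class %in% c("character", "numeric"),
            uniqueness %in% c("unique", "nonunique"),
            allowed_analysis %in% c("any", "subset", "wholeset", "range"))
  if (allowed_analysis == "range") {
    if (class != "numeric") stop("range analysis requires class numeric")
    allowed_values <- as.numeric(allowed_values)
    if (length(allowed_values) != 2 || anyNA(allowed_values)) {
      stop("range analysis needs numeric bounds c(min, max)")
    }
  }
  if (allowed_analysis == "any" && length(allowed_values)) {
    stop("allowed_values must be empty for analysis 'any'")
  }
  if (allowed_analysis %in% c("subset", "wholeset") && !length(allowed_values)) {
    stop(allowed_analysis, " analysis needs allowed values")
  }
  structure(list(name = name, requiredness = requiredness, class = class,
                 uniqueness = uniqueness, allowed_analysis = allowed_analysis,
                 allowed_values = allowed_values,
                 crosscheck_variables = as.character(crosscheck_variables)),
            class = "variable_spec")
}

#' Read a variables dictionary
#'
#' A TSV with one row per variable and columns `name`, `requiredness`,
#' `class`, `uniqueness`, `allowed_analysis`, `allowed_values`
#' (";"-separated; `min..max` for ranges) and `crosscheck_variables`
#' (";"-separated). Names must be unique and crosscheck references must
#' resolve within the dictionary.
#'
#' @param path Path to the TSV.
#' @return A `variables_dictionary`: named list of [variable_spec()]
#'   objects in file order.
#' @export
read_variables_dictionary <- function(path) {
  tab <- read_metadata_table(path)
  absent <- setdiff(.dictionary_columns, names(tab))
  if (length(absent)) {
    stop("dictionary is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    analysis <- if (is.na(tab$allowed_analysis[i])) "any" else tab$allowed_analysis[i]
    raw_allowed <- tab$allowed_values[i]
    allowed <- if (analysis == "range") {
      if (is.na(raw_allowed) || !grepl("^-?[0-9.]+\\.\\.-?[0-9.]+$", raw_allowed)) {
        stop("range bounds must be written min..max for variable ",
             tab$name[i], call. = FALSE)
      }
      as.numeric(strsplit(raw_allowed, "..", fixed = TRUE)[[1]])
    } else split_multivalue(raw_allowed)
    variable_spec(
      name = tab$name[i],
      requiredness = tab$requiredness[i],
      class = tab$class[i],
      uniqueness = tab$uniqueness[i],
      allowed_analysis = analysis,
      allowed_values = allowed,
      crosscheck_variables = split_multivalue(tab$crosscheck_variables[i]))
  })
  new_variables_dictionary(specs)
}

#' Assemble a variables dictionary from specs
#'
#' @param specs List of [variable_spec()] objects.
#' @return A `variables_dictionary`.
#' @export
new_variables_dictionary <- function(specs) {
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicated variable names in dictionary: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  unresolved <- setdiff(unlist(lapply(specs, `[[`, "crosscheck_variables")), nm)
  if (length(unresolved)) {
    stop("crosscheck references undefined variable(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(specs, nm), class = "variables_dictionary")
}

#' Write a variables dictionary
#'
#' @param dictionary A `variables_dictionary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variables_dictionary <- function(dictionary, path) {
  tab <- data.frame(
    name = vapply(dictionary, `[[`, "", "name"),
    requiredness = vapply(dictionary, `[[`, "", "requiredness"),
    class = vapply(dictionary, `[[`, "", "class"),
    uniqueness = vapply(dictionary, `[[`, "", "uniqueness"),
    allowed_analysis = vapply(dictionary, `[[`, "", "allowed_analysis"),
    allowed_values = vapply(dictionary, function(s) {
      if (s$allowed_analysis == "range") {
        paste(format(s$allowed_values, trim = TRUE), collapse = "..")
      } else paste(s$allowed_values, collapse = ";")
    }, ""),
    crosscheck_variables = vapply(dictionary, function(s)
      paste(s$crosscheck_variables, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  write_metadata_table(tab, path)
}

#' Validate one variable of a table against its spec
#'
#' The checks run in a fixed order and the later ones only when the
#' variable is present: (1) presence according to requiredness;
#' (2) class (numeric cells must parse as numbers; character accepts any
#' string including boolean tokens); (3) uniqueness; (4) multi-match
#' crosschecks against the listed variables, run in both directions;
#' (5) the allowed-value analysis (any / subset / wholeset / range, range
#' bounds inclusive). Missing cells never violate the class, uniqueness
#' or allowed analyses — missingness is governed by requiredness alone.
#'
#' @param spec A [variable_spec()].
#' @param table Metadata data frame.
#' @return List of findings.
#' @export
check_variable <- function(spec, table) {
  findings <- list()
  if (!spec$name %in% names(table)) {
    code <- if (spec$requiredness == "required") "VARIABLE_MISSING" else "VARIABLE_OPTIONAL_ABSENT"
    return(list(finding(code, subjects = spec$name,
                        message = sprintf("%s variable %s is absent from the table",
                                          spec$requiredness, spec$name))))
  }
  vals <- table[[spec$name]]
  nn <- vals[!is.na(vals)]
  if (spec$class == "numeric") {
    bad <- unique(nn[!grepl(.numeric_cell_re, nn)])
    if (length(bad)) {
      findings <- c(findings, list(finding(
        "VARIABLE_NOT_NUMERIC", subjects = c(spec$name, bad),
        message = sprintf("variable %s has non-numeric value(s): %s",
                          spec$name, paste(bad, collapse = ", ")))))
    }
  }
  if (spec$uniqueness == "unique") {
    dup <- sort(unique(nn[duplicated(nn)]))
    if (length(dup)) {
      findings <- c(findings, list(finding(
        "VARIABLE_NOT_UNIQUE", subjects = c(spec$name, dup),
        message = sprintf("variable %s has duplicated value(s): %s",
                          spec$name, paste(dup, collapse = ", ")))))
    }
  }
  for (v in spec$crosscheck_variables) {
    if (!v %in% names(table)) next
    for (direction in list(c(spec$name, v), c(v, spec$name))) {
      a <- table[[direction[1]]]; b <- table[[direction[2]]]
      keep <- !is.na(a) & !is.na(b)
      bad <- names(which(vapply(split(b[keep], a[keep]),
                                function(x) length(unique(x)) > 1, TRUE)))
      if (length(bad)) {
        findings <- c(findings, list(finding(
          "VARIABLE_MULTIMATCH", subjects = c(direction, sort(bad)),
          message = sprintf("value(s) of %s mapping to several values of %s: %s",
                            direction[1], direction[2],
                            paste(sort(bad), collapse = ", ")))))
      }
    }
  }
  if (spec$allowed_analysis == "subset") {
    outliers <- sort(setdiff(unique(nn), spec$allowed_values))
    if (length(outliers)) {
      findings <- c(findings, list(finding(
        "VALUE_NOT_ALLOWED", subjects = c(spec$name, outliers),
        message = sprintf("variable %s has disallowed value(s): %s",
                          spec$name, paste(outliers, collapse = ", ")))))
    }
  } else if (spec$allowed_analysis == "wholeset") {
    extra <- sort(setdiff(unique(nn), spec$allowed_values))
    uncovered <- sort(setdiff(spec$allowed_values, unique(nn)))
    if (length(extra) || length(uncovered)) {
      findings <- c(findings, list(finding(
        "VALUE_SET_MISMATCH", subjects = c(spec$name, extra, uncovered),
        message = sprintf(
          "variable %s: observed set != allowed set (disallowed: %s; uncovered: %s)",
          spec$name,
          if (length(extra)) paste(extra, collapse = ", ") else "none",
          if (length(uncovered)) paste(uncovered, collapse = ", ") else "none"))))
    }
  } else if (spec$allowed_analysis == "range") {
    num <- suppressWarnings(as.numeric(nn[grepl(.numeric_cell_re, nn)]))
    out <- sort(unique(num[num < spec$allowed_values[1] |
                             num > spec$allowed_values[2]]))
    if (length(out)) {
      findings <- c(findings, list(finding(
        "VALUE_OUT_OF_RANGE", subjects = c(spec$name, format(out, trim = TRUE)),
        message = sprintf("variable %s has value(s) outside [%s, %s]: %s",
                          spec$name, format(spec$allowed_values[1]),
                          format(spec$allowed_values[2]),
                          paste(format(out, trim = TRUE), collapse = ", ")))))
    }
  }
  findings
}

#' Validate a curated table against a variables dictionary
#'
#' Runs [check_variable()] for every dictionary entry in dictionary
#' order and notes table columns that the dictionary does not declare.
#'
#' @param dictionary A `variables_dictionary`.
#' @param table Metadata data frame.
#' @return A `curation_report`.
#' @export
check_metadata_values <- function(dictionary, table) {
  if (!inherits(dictionary, "variables_dictionary")) {
    stop("dictionary must be a variables_dictionary", call. = FALSE)
  }
  findings <- list()
  for (spec in dictionary) {
    findings <- c(findings, check_variable(spec, table))
  }
  for (col in setdiff(names(table), names(dictionary))) {
    findings <- c(findings, list(finding(
      "UNDECLARED_VARIABLE", subjects = col,
      message = sprintf("table column %s is not declared in the dictionary", col))))
  }
  tally <- table(factor(vapply(findings, `[[`, "", "severity"),
                        levels = .severity_levels))
  check_report(findings, list(`finding severities` = as.data.frame(tally,
                                                                   stringsAsFactors = FALSE)))
}

#' Concatenate the curated tables of several datasets
#'
#' Each table must first pass [check_metadata_values()] without errors
#' (warnings are tolerated); the function aborts on the first failing
#' table. The output has the dictionary variables as columns (dictionary
#' order), the tables' rows appended in input order with absent optional
#' columns filled as missing, and a `dataset_origin` column naming the
#' source dataset. Every `uniqueness = unique` variable is then
#' re-checked across datasets: values occurring in more than one dataset
#' are reported as CROSS_DATASET_DUPLICATE.
#'
#' @param tables List of at least two metadata data frames.
#' @param dictionary A `variables_dictionary`.
#' @param dataset_names Origin labels; defaults to `dataset_1`, ...
#' @return List with `table` and `findings`.
#' @export
concat_datasets <- function(tables, dictionary, dataset_names = NULL) {
  if (length(tables) < 2) stop("need at least two tables", call. = FALSE)
  if (is.null(dataset_names)) {
    dataset_names <- paste0("dataset_", seq_along(tables))
  }
  stopifnot(length(dataset_names) == length(tables))
  for (i in seq_along(tables)) {
    vrep <- check_metadata_values(dictionary, tables[[i]])
    if (vrep$status == "error") {
      stop(sprintf("table %s fails validation:\n%s", dataset_names[i],
                   paste(vapply(vrep$findings, format_finding, ""),
                         collapse = "\n")),
           call. = FALSE)
    }
  }
  cols <- names(dictionary)
  parts <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    for (col in setdiff(cols, names(t))) t[[col]] <- NA_character_
    t <- t[cols]
    t$dataset_origin <- rep(dataset_names[i], nrow(t))
    t
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  findings <- list()
  for (spec in dictionary) {
    if (spec$uniqueness != "unique") next
    vals <- out[[spec$name]]
    origin <- out$dataset_origin
    keep <- !is.na(vals)
    per_value <- split(origin[keep], vals[keep])
    dup <- names(which(vapply(per_value,
                              function(o) length(unique(o)) > 1, TRUE)))
    for (v in sort(dup)) {
      findings <- c(findings, list(finding(
        "CROSS_DATASET_DUPLICATE", subjects = c(spec$name, v),
        message = sprintf("unique variable %s: value %s occurs in datasets %s",
                          spec$name, v,
                          paste(sort(unique(per_value[[v]])), collapse = ", ")))))
    }
  }
  list(table = out, findings = findings)
}

#' Derive a curated-table dictionary from a run-level one
#'
#' After [treat_metadata()] the table has one row per sample: the sample
#' column becomes the unique identifier while run-specific columns hold
#' ";"-joined lists and can no longer satisfy value analyses. This
#' helper rewrites a run-level dictionary accordingly.
#'
#' @param dictionary Run-level `variables_dictionary`.
#' @param sample_variable Variable that identifies the sample.
#' @param run_specific Variables relaxed to nonunique/any; see
#'   [run_specific_columns()].
#' @return A `variables_dictionary` for the curated per-sample table.
#' @export
curated_dictionary <- function(dictionary,
                               sample_variable = "sample_accession",
                               run_specific = run_specific_columns()) {
  specs <- lapply(dictionary, function(s) {
    if (s$name == sample_variable) {
      s$uniqueness <- "unique"
    } else if (s$name %in% run_specific) {
      s$uniqueness <- "nonunique"
      s$allowed_analysis <- "any"
      s$allowed_values <- character()
      s$class <- "character"
    }
    s
  })
  new_variables_dictionary(unname(specs))
}
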