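# Merge Metadata and Filter Metadata: combining metadata sources and
# applying sequential row filters driven by an archivable control file.

trim_key <- function(x) {
  out <- trimws(as.character(x))
  out[is.na(x)] <- NA_character_
  out
}

#' Merge two metadata tables on a key pair
#'
#' Relational join of a main table (left reference) and an extra table,
#' typically the archive metadata and the publication's supplementary
#' table. Keys are compared by exact string equality after trimming
#' surrounding whitespace; missing keys never match. Column-name
#' collisions between the two tables are suffixed `_main` / `_extra`.
#' The unique key values found only in one source are reported (info when
#' the difference is empty, warning otherwise), and an extra key matching
#' several extra rows fans the main row out and is reported as
#' KEY_MULTIMATCH.
#'
#' @param main Main (left) data frame.
#' @param extra Extra (right) data frame.
#' @param main_key,extra_key Key column names in their tables.
#' @param mode Join mode: `"left"` (default), `"right"`, `"inner"` or
#'   `"outer"`.
#' @return List with `table` (the merged data frame) and `findings`.
#' @export
merge_metadata <- function(main, extra, main_key, extra_key,
                           mode = c("left", "right", "inner", "outer")) {
  mode <- match.arg(mode)
  if (!main_key %in% names(main)) stop("key column not in main table: ", main_key, call. = FALSE)
  if (!extra_key %in% names(extra)) stop("key column not in extra table: ", extra_key, call. = FALSE)

  mk <- trim_key(main[[main_key]])
  ek <- trim_key(extra[[extra_key]])

  findings <- list()
  main_only <- sort(setdiff(distinct_values(mk), distinct_values(ek)))
  extra_only <- sort(setdiff(distinct_values(ek), distinct_values(mk)))
  if (length(main_only)) {
    findings <- c(findings, list(finding(
      "MERGE_MAIN_ONLY_KEYS", subjects = main_only,
      message = sprintf("%d key value(s) only in the main table: %s",
                        length(main_only), paste(main_only, collapse = ", ")))))
  } else {
    findings <- c(findings, list(finding(
      "MERGE_KEYS_ALIGNED", subjects = "main",
      message = "every main key value is present in the extra table")))
  }
  if (length(extra_only)) {
    findings <- c(findings, list(finding(
      "MERGE_EXTRA_ONLY_KEYS", subjects = extra_only,
      message = sprintf("%d key value(s) only in the extra table: %s",
                        length(extra_only), paste(extra_only, collapse = ", ")))))
  } else {
    findings <- c(findings, list(finding(
      "MERGE_KEYS_ALIGNED", subjects = "extra",
      message = "every extra key value is present in the main table")))
  }
  multi <- sort(unique(ek[!is.na(ek)][duplicated(ek[!is.na(ek)])]))
  multi <- multi[multi %in% mk]
  if (length(multi)) {
    findings <- c(findings, list(finding(
      "KEY_MULTIMATCH", subjects = multi,
      message = sprintf("extra key value(s) matching several extra rows fan out: %s",
                        paste(multi, collapse = ", ")))))
  }

  extra_cols <- setdiff(names(extra), extra_key)
  shared <- intersect(names(main), extra_cols)
  main_names <- names(main)
  main_names[main_names %in% shared] <- paste0(main_names[main_names %in% shared], "_main")
  out_extra_names <- ifelse(extra_cols %in% shared, paste0(extra_cols, "_extra"), extra_cols)
  main_key_out <- main_names[match(main_key, names(main))]

  row_vec <- function(df, i, cols = names(df)) {
    vapply(cols, function(cn) as.character(df[[cn]])[i], "")
  }
  na_main <- rep(NA_character_, ncol(main))
  na_extra <- rep(NA_character_, length(extra_cols))

  pieces <- list()
  if (mode %in% c("left", "inner", "outer")) {
    for (i in seq_len(nrow(main))) {
      hits <- if (is.na(mk[i])) integer() else which(!is.na(ek) & ek == mk[i])
      if (length(hits)) {
        for (j in hits) {
          pieces[[length(pieces) + 1]] <-
            c(row_vec(main, i), row_vec(extra, j, extra_cols))
        }
      } else if (mode != "inner") {
        pieces[[length(pieces) + 1]] <- c(row_vec(main, i), na_extra)
      }
    }
  }
  if (mode %in% c("right", "outer")) {
    for (j in seq_len(nrow(extra))) {
      hits <- if (is.na(ek[j])) integer() else which(!is.na(mk) & mk == ek[j])
      if (mode == "right" && length(hits)) {
        for (i in hits) {
          pieces[[length(pieces) + 1]] <-
            c(row_vec(main, i), row_vec(extra, j, extra_cols))
        }
      } else if (!length(hits)) {
        left <- na_main
        left[match(main_key, names(main))] <- ek[j] # keep the key visible
        pieces[[length(pieces) + 1]] <- c(left, row_vec(extra, j, extra_cols))
      }
    }
  }

  out_names <- c(main_names, out_extra_names)
  mat <- if (length(pieces)) do.call(rbind, pieces) else
    matrix(character(), 0, length(out_names))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- out_names
  rownames(out) <- NULL
  list(table = out, findings = findings)
}

.filter_modes <- c("keep_values", "drop_values", "numeric")
.filter_operators <- c("<", "<=", ">", ">=", "==", "!=")
.numeric_cell_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$"

#' Construct one filter step
#'
#' @param column Column the step applies to.
#' @param mode `"keep_values"`, `"drop_values"` (categorical; use
#'   `values`) or `"numeric"` (use `operator` and `threshold`).
#' @param values Character vector of category values (categorical modes).
#' @param operator Comparison operator (numeric mode): one of
#'   `<, <=, >, >=, ==, !=`.
#' @param threshold Numeric threshold (numeric mode).
#' @param na_policy `"keep"` or `"drop"`: whether rows with a missing
#'   cell in `column` survive this step.
#' @return A `filter_step` list.
#' @export
filter_step <- function(column, mode, values = NULL, operator = NULL,
                        threshold = NULL, na_policy = c("keep", "drop")) {
  na_policy <- match.arg(na_policy)
  if (!is.character(column) || !nzchar(column)) stop("column must be non-empty")
  if (!mode %in% .filter_modes) stop("unknown filter mode: ", mode)
  if (mode == "numeric") {
    if (is.null(operator) || !operator %in% .filter_operators) {
      stop("numeric mode needs an operator from: ",
           paste(.filter_operators, collapse = " "))
    }
    if (is.null(threshold) || is.na(suppressWarnings(as.numeric(threshold)))) {
      stop("numeric mode needs a numeric threshold")
    }
    if (!is.null(values) && length(values)) stop("numeric mode takes no values")
    values <- NULL
    threshold <- as.numeric(threshold)
  } else {
    if (is.null(values) || !length(values)) stop(mode, " needs values")
    if (!is.null(operator) || !is.null(threshold)) {
      stop("categorical modes take no operator/threshold")
    }
  }
  structure(list(column = column, mode = mode, values = values,
                 operator = operator, threshold = threshold,
                 na_policy = na_policy),
            class = "filter_step")
}

#' Read a filter specification file
#'
#' A TSV control file with one filter step per row (execution order =
#' file order) and columns `column`, `mode`, `operator`, `values`,
#' `na_policy`; `values` holds the ";"-separated category values, or the
#' numeric threshold for numeric steps.
#'
#' @param path Path to the TSV.
#' @return List of [filter_step()] objects.
#' @export
read_filter_spec <- function(path) {
  tab <- read_metadata_table(path)
  need <- c("column", "mode", "operator", "values", "na_policy")
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stop("filter spec is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    mode <- tab$mode[i]
    na_policy <- if (is.na(tab$na_policy[i])) "keep" else tab$na_policy[i]
    if (identical(mode, "numeric")) {
      filter_step(tab$column[i], mode, operator = tab$operator[i],
                  threshold = tab$values[i], na_policy = na_policy)
    } else {
      filter_step(tab$column[i], mode, values = split_multivalue(tab$values[i]),
                  na_policy = na_policy)
    }
  })
}

#' Write a filter specification file
#'
#' @param steps List of [filter_step()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_filter_spec <- function(steps, path) {
  tab <- data.frame(
    column = vapply(steps, `[[`, "", "column"),
    mode = vapply(steps, `[[`, "", "mode"),
    operator = vapply(steps, function(s) if (is.null(s$operator)) NA_character_ else s$operator, ""),
    values = vapply(steps, function(s) {
      if (s$mode == "numeric") format(s$threshold) else paste(s$values, collapse = ";")
    }, ""),
    na_policy = vapply(steps, `[[`, "", "na_policy"),
    stringsAsFactors = FALSE
  )
  write_metadata_table(tab, path)
}

apply_filter_step <- function(table, step, step_index) {
  if (!step$column %in% names(table)) {
    stop(sprintf("filter step %d references absent column '%s'",
                 step_index, step$column), call. = FALSE)
  }
  cell <- table[[step$column]]
  keep <- switch(step$mode,
    keep_values = cell %in% step$values,
    drop_values = !(cell %in% step$values),
    numeric = {
      bad <- !is.na(cell) & !grepl(.numeric_cell_re, cell)
      if (any(bad)) {
        stop(sprintf("CELL_NOT_NUMERIC: step %d, column '%s', row(s) %s: %s",
                     step_index, step$column,
                     paste(which(bad), collapse = ", "),
                     paste(unique(cell[bad]), collapse = ", ")),
             call. = FALSE)
      }
      do.call(step$operator, list(as.numeric(cell), step$threshold))
    })
  keep[is.na(cell)] <- identical(step$na_policy, "keep")
  keep
}

#' Filter a metadata table through sequential steps
#'
#' Applies the steps of a filter specification strictly in order;
#' `keep_values` retains rows whose cell is among the listed values,
#' `drop_values` removes them, `numeric` parses the cell (integers and
#' "."-decimals only) and applies the comparison. Rows with a missing
#' cell survive a step iff its `na_policy` is `"keep"`.
#'
#' @param table Metadata data frame.
#' @param steps List of [filter_step()] objects (e.g. from
#'   [read_filter_spec()]).
#' @return List with `table` (the filtered data frame) and `report`, a
#'   data frame with one row per step: `step`, `column`, `mode`,
#'   `rows_before`, `rows_removed`, `rows_after`.
#' @export
filter_metadata <- function(table, steps) {
  rows_before <- integer(); rows_removed <- integer(); rows_after <- integer()
  for (i in seq_along(steps)) {
    before <- nrow(table)
    keep <- apply_filter_step(table, steps[[i]], i)
    table <- table[keep, , drop = FALSE]
    rownames(table) <- NULL
    rows_before[i] <- before
    rows_after[i] <- nrow(table)
    rows_removed[i] <- before - nrow(table)
  }
  report <- data.frame(
    step = seq_along(steps),
    column = vapply(steps, `[[`, "", "column"),
    mode = vapply(steps, `[[`, "", "mode"),
    rows_before = rows_before,
    rows_removed = rows_removed,
    rows_after = rows_after,
    stringsAsFactors = FALSE
  )
  if (!length(steps)) {
    report <- data.frame(step = integer(), column = character(),
                         mode = character(), rows_before = integer(),
                         rows_removed = integer(), rows_after = integer(),
                         stringsAsFactors = FALSE)
  }
  list(table = table, report = report)
}
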