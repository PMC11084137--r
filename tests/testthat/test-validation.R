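base_table <- function() {
  data.frame(subject_id = c("P01", "P02", "P03"),
             group = c("case", "control", "case"),
             age = c("34", "61", "18"),
             stringsAsFactors = FALSE)
}

test_that("variable specs enforce their own invariants", {
  expect_error(variable_spec("x", allowed_analysis = "range"),
               "requires class numeric")
  expect_error(variable_spec("x", class = "numeric",
                             allowed_analysis = "range",
                             allowed_values = c(1, 2, 3)), "bounds")
  expect_error(variable_spec("x", allowed_analysis = "any",
                             allowed_values = "a"), "empty")
  expect_error(variable_spec("x", allowed_analysis = "subset"), "allowed values")
  expect_error(new_variables_dictionary(list(variable_spec("a"),
                                             variable_spec("a"))),
               "duplicated")
  expect_error(new_variables_dictionary(list(
    variable_spec("a", crosscheck_variables = "ghost"))), "undefined")
})

test_that("dictionaries round-trip through their TSV format", {
  d <- tmp_dir()
  dict <- new_variables_dictionary(list(
    variable_spec("subject_id", "required", "character", "unique",
                  crosscheck_variables = "group"),
    variable_spec("group", "required", "character", "nonunique",
                  allowed_analysis = "subset",
                  allowed_values = c("case", "control")),
    variable_spec("age", "optional", "numeric", "nonunique",
                  allowed_analysis = "range", allowed_values = c(0, 120))))
  p <- file.path(d, "dict.tsv")
  write_variables_dictionary(dict, p)
  back <- read_variables_dictionary(p)
  expect_equal(names(back), c("subject_id", "group", "age"))
  expect_equal(back$age$allowed_values, c(0, 120))
  expect_equal(back$group$allowed_values, c("case", "control"))
  expect_equal(back$subject_id$crosscheck_variables, "group")
})

test_that("presence and class checks behave per requiredness and type", {
  tab <- base_table()
  req <- variable_spec("height", "required")
  expect_equal(findings_table(check_variable(req, tab))$code, "VARIABLE_MISSING")
  opt <- variable_spec("height", "optional")
  expect_equal(findings_table(check_variable(opt, tab))$code,
               "VARIABLE_OPTIONAL_ABSENT")

  num <- variable_spec("group", class = "numeric")
  f <- check_variable(num, tab)
  expect_equal(finding_codes(f), "VARIABLE_NOT_NUMERIC")
  expect_true(all(c("case", "control") %in% f[[1]]$subjects))

  # boolean tokens pass as character; missing cells never fail class
  tab$flag <- c("true", "FALSE", NA)
  expect_length(check_variable(variable_spec("flag"), tab), 0)
  tab$age[2] <- NA
  expect_length(check_variable(variable_spec("age", class = "numeric"), tab), 0)
})

test_that("uniqueness and crosscheck multi-matches are reported", {
  tab <- base_table()
  tab$subject_id[3] <- "P01"
  f <- check_variable(variable_spec("subject_id", uniqueness = "unique"), tab)
  expect_equal(finding_codes(f), "VARIABLE_NOT_UNIQUE")
  expect_true("P01" %in% f[[1]]$subjects)

  # P01 maps to both case and control -> multimatch in one direction
  tab2 <- base_table()
  tab2$subject_id <- c("P01", "P01", "P02")
  tab2$group <- c("case", "control", "case")
  f <- check_variable(variable_spec("subject_id",
                                    crosscheck_variables = "group"), tab2)
  expect_equal(finding_codes(f), "VARIABLE_MULTIMATCH")
  expect_true("P01" %in% f[[1]]$subjects)
})

test_that("subset, wholeset and range agree with set/interval oracles", {
  tab <- base_table()
  sub <- variable_spec("group", allowed_analysis = "subset",
                       allowed_values = c("case", "control", "other"))
  expect_length(check_variable(sub, tab), 0) # observed strictly inside allowed

  whole <- variable_spec("group", allowed_analysis = "wholeset",
                         allowed_values = c("case", "control", "other"))
  f <- check_variable(whole, tab)
  expect_equal(finding_codes(f), "VALUE_SET_MISMATCH")
  expect_true("other" %in% f[[1]]$subjects) # uncovered allowed value

  rng <- variable_spec("age", class = "numeric", allowed_analysis = "range",
                       allowed_values = c(0, 120))
  expect_length(check_variable(rng, tab), 0)
  tab$age[1] <- "134"
  f <- check_variable(rng, tab)
  expect_equal(finding_codes(f), "VALUE_OUT_OF_RANGE")
  expect_true("134" %in% f[[1]]$subjects)
  tab$age[1] <- "120" # inclusive upper bound
  expect_length(check_variable(rng, tab), 0)
})

test_that("randomized specs agree with independent set/interval oracles", {
  set.seed(606)
  pool <- c("a", "b", "c", "d", "e")
  for (i in 1:30) {
    n <- sample(1:20, 1)
    vals <- sample(c(pool, NA), n, replace = TRUE)
    tab <- data.frame(v = vals, stringsAsFactors = FALSE)
    allowed <- sample(pool, sample(1:5, 1))
    obs <- unique(vals[!is.na(vals)])
    f_sub <- check_variable(variable_spec("v", allowed_analysis = "subset",
                                          allowed_values = allowed), tab)
    expect_equal(length(f_sub) > 0, !all(obs %in% allowed))
    f_whole <- check_variable(variable_spec("v", allowed_analysis = "wholeset",
                                            allowed_values = allowed), tab)
    expect_equal(length(f_whole) > 0, !setequal(obs, allowed))

    nums <- sample(0:50, n, replace = TRUE)
    ntab <- data.frame(v = as.character(nums), stringsAsFactors = FALSE)
    lo <- sample(0:20, 1); hi <- lo + sample(5:25, 1)
    f_rng <- check_variable(variable_spec("v", class = "numeric",
                                          allowed_analysis = "range",
                                          allowed_values = c(lo, hi)), ntab)
    expect_equal(length(f_rng) > 0, any(nums < lo | nums > hi))
  }
})

test_that("check families are reported in their fixed order", {
  tab <- data.frame(v = c("x", "x", "5"), w = c("1", "2", "3"),
                    stringsAsFactors = FALSE)
  spec <- variable_spec("v", class = "numeric", uniqueness = "unique",
                        allowed_analysis = "subset", allowed_values = "5",
                        crosscheck_variables = "w")
  codes <- findings_table(check_variable(spec, tab))$code
  expect_equal(codes, c("VARIABLE_NOT_NUMERIC", "VARIABLE_NOT_UNIQUE",
                        "VARIABLE_MULTIMATCH", "VALUE_NOT_ALLOWED"))
})

test_that("whole-table validation composes specs plus undeclared columns", {
  dict <- new_variables_dictionary(list(
    variable_spec("subject_id", "required", uniqueness = "unique"),
    variable_spec("group", "required", allowed_analysis = "subset",
                  allowed_values = c("case", "control")),
    variable_spec("age", "optional", class = "numeric")))
  tab <- base_table()
  rep <- check_metadata_values(dict, tab)
  expect_equal(rep$status, "info")

  tab$notes <- "free text"
  rep <- check_metadata_values(dict, tab)
  expect_equal(findings_table(rep$findings)$code, "UNDECLARED_VARIABLE")

  tab$group[1] <- "mystery"
  rep <- check_metadata_values(dict, tab)
  expect_equal(rep$status, "error")
  expect_equal(finding_codes(rep$findings), "VALUE_NOT_ALLOWED")
})

test_that("dataset concatenation pads, orders and re-checks uniqueness", {
  dict <- new_variables_dictionary(list(
    variable_spec("subject_id", "required", uniqueness = "unique"),
    variable_spec("group", "required"),
    variable_spec("age", "optional", class = "numeric")))
  t1 <- data.frame(subject_id = c("P01", "P02"), group = "case",
                   age = c("40", "50"), stringsAsFactors = FALSE)
  t2 <- data.frame(group = "control", subject_id = c("Q01", "Q02", "Q03"),
                   stringsAsFactors = FALSE) # age absent, columns shuffled
  res <- concat_datasets(list(t1, t2), dict)
  expect_equal(nrow(res$table), 5) # row-count additivity
  expect_equal(names(res$table), c("subject_id", "group", "age", "dataset_origin"))
  expect_true(all(is.na(res$table$age[3:5]))) # optional padding
  expect_equal(res$table$dataset_origin, rep(c("dataset_1", "dataset_2"), c(2, 3)))
  expect_length(res$findings, 0)

  t2$subject_id[1] <- "P01"
  res <- concat_datasets(list(t1, t2), dict)
  f <- findings_table(res$findings)
  expect_equal(f$code, "CROSS_DATASET_DUPLICATE")
  expect_true(grepl("P01", f$subjects))

  bad <- t1; bad$subject_id <- NULL
  expect_error(concat_datasets(list(bad, t2), dict), "fails validation")
  expect_error(concat_datasets(list(t1), dict), "at least two")
})

test_that("validating a concatenated output adds no new error families", {
  dict <- new_variables_dictionary(list(
    variable_spec("subject_id", "required", uniqueness = "unique"),
    variable_spec("group", "required", allowed_analysis = "subset",
                  allowed_values = c("case", "control"))))
  t1 <- data.frame(subject_id = c("P01", "P02"), group = c("case", "control"),
                   stringsAsFactors = FALSE)
  t2 <- data.frame(subject_id = c("P01", "P09"), group = "case",
                   stringsAsFactors = FALSE)
  res <- concat_datasets(list(t1, t2), dict)
  again <- check_metadata_values(dict, res$table)
  new_codes <- finding_codes(again$findings)
  # the cross-dataset duplicate resurfaces as a uniqueness violation only
  expect_true(all(new_codes %in% c("VARIABLE_NOT_UNIQUE")))
})
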