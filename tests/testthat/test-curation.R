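test_that("merge reproduces the documented key-set examples", {
  main <- data.frame(id = c("A", "B", "C"), x = c("1", "2", "3"),
                     stringsAsFactors = FALSE)
  extra <- data.frame(key = c("B", "C", "D"), y = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  res <- merge_metadata(main, extra, "id", "key", "left")
  expect_equal(nrow(res$table), 3)
  expect_equal(res$table$y, c(NA, "b", "c"))
  tabf <- findings_table(res$findings)
  expect_equal(sort(tabf$code[tabf$severity == "warning"]),
               c("MERGE_EXTRA_ONLY_KEYS", "MERGE_MAIN_ONLY_KEYS"))
  expect_equal(tabf$subjects[tabf$code == "MERGE_MAIN_ONLY_KEYS"], "A")
  expect_equal(tabf$subjects[tabf$code == "MERGE_EXTRA_ONLY_KEYS"], "D")

  # empty extra is the neutral element of the left join
  none <- data.frame(key = character(), y = character(), stringsAsFactors = FALSE)
  res <- merge_metadata(main, none, "id", "key", "left")
  expect_equal(res$table$id, main$id)
  expect_true(all(is.na(res$table$y)))

  # fan-out on a duplicated extra key
  dup <- data.frame(key = c("B", "B", "C"), y = c("b1", "b2", "c"),
                    stringsAsFactors = FALSE)
  res <- merge_metadata(main, dup, "id", "key", "left")
  expect_equal(nrow(res$table), 4)
  expect_true("KEY_MULTIMATCH" %in% findings_table(res$findings)$code)
})

test_that("merge handles collisions, trimming and the outer modes", {
  main <- data.frame(id = c("A", "B"), note = c("m1", "m2"),
                     stringsAsFactors = FALSE)
  extra <- data.frame(key = c(" B ", "D"), note = c("e1", "e2"),
                      stringsAsFactors = FALSE)
  res <- merge_metadata(main, extra, "id", "key", "outer")
  expect_equal(names(res$table), c("id", "note_main", "note_extra"))
  expect_equal(nrow(res$table), 3) # A unmatched, B matched (trimmed), D extra-only
  expect_equal(res$table$id, c("A", "B", "D"))
  expect_equal(res$table$note_extra, c(NA, "e1", "e2"))

  res <- merge_metadata(main, extra, "id", "key", "inner")
  expect_equal(res$table$id, "B")
  res <- merge_metadata(main, extra, "id", "key", "right")
  expect_equal(res$table$id, c("B", "D"))
  expect_error(merge_metadata(main, extra, "nope", "key"), "key column")
})

test_that("all four join modes agree with a brute-force oracle", {
  set.seed(303)
  modes <- c("left", "right", "inner", "outer")
  for (i in 1:40) {
    keys <- c(LETTERS[1:6], NA)
    main <- data.frame(k = sample(keys, sample(1:10, 1), replace = TRUE),
                       a = rand_token(1), stringsAsFactors = FALSE)
    extra <- data.frame(kk = sample(keys, sample(1:10, 1), replace = TRUE),
                        b = rand_token(1), stringsAsFactors = FALSE)
    main$a <- rand_token(nrow(main)); extra$b <- rand_token(nrow(extra))
    mode <- modes[(i - 1) %% 4 + 1]
    res <- merge_metadata(main, extra, "k", "kk", mode)
    expect_equal(nrow(res$table),
                 join_oracle_nrow(main$k, extra$kk, mode),
                 label = sprintf("iteration %d mode %s", i, mode))
  }
})

test_that("left join with unique extra keys preserves main's row count", {
  set.seed(404)
  for (i in 1:15) {
    main <- data.frame(k = sample(LETTERS, sample(1:12, 1), replace = TRUE),
                       stringsAsFactors = FALSE)
    extra <- data.frame(kk = sample(LETTERS, sample(1:12, 1)), # unique draw
                        v = "x", stringsAsFactors = FALSE)
    res <- merge_metadata(main, extra, "k", "kk", "left")
    expect_equal(nrow(res$table), nrow(main))
  }
})

test_that("filter steps apply sequentially with explicit NA policy", {
  tab <- data.frame(group = c("case", "case", "control", NA, "other"),
                    age = c("40", "17", "65", "30", NA),
                    stringsAsFactors = FALSE)
  keep <- filter_step("group", "keep_values", values = "case",
                      na_policy = "keep")
  res <- filter_metadata(tab, list(keep))
  expect_equal(nrow(res$table), 3) # 2 matches + 1 NA kept

  drop_na <- filter_step("group", "keep_values", values = "case",
                         na_policy = "drop")
  expect_equal(nrow(filter_metadata(tab, list(drop_na))$table), 2)

  adult <- filter_step("age", "numeric", operator = ">=", threshold = 18,
                       na_policy = "drop")
  res <- filter_metadata(tab, list(keep, adult))
  expect_equal(res$table$age, c("40", "30"))
  expect_equal(res$report$rows_before, c(5, 3))
  expect_equal(res$report$rows_after, c(3, 2))
  expect_equal(res$report$rows_before - res$report$rows_removed,
               res$report$rows_after)

  # vacuous numeric comparison on an all-missing column
  tab$height <- NA_character_
  res <- filter_metadata(tab, list(filter_step("height", "numeric",
                                               operator = ">=", threshold = 0,
                                               na_policy = "drop")))
  expect_equal(nrow(res$table), 0)
})

test_that("filter errors name the step and the offending cells", {
  tab <- data.frame(age = c("40", "unknown"), stringsAsFactors = FALSE)
  step <- filter_step("age", "numeric", operator = "<", threshold = 50)
  expect_error(filter_metadata(tab, list(step)), "CELL_NOT_NUMERIC.*age")
  gone <- filter_step("weight", "keep_values", values = "x")
  expect_error(filter_metadata(tab, list(gone)), "step 1.*weight")
  expect_error(filter_step("age", "numeric", operator = "~", threshold = 1),
               "operator")
  expect_error(filter_step("age", "keep_values"), "values")
})

test_that("filter specifications round-trip through their control file", {
  d <- tmp_dir()
  steps <- list(
    filter_step("group", "keep_values", values = c("case", "control"),
                na_policy = "drop"),
    filter_step("age", "numeric", operator = ">=", threshold = 18.5),
    filter_step("site", "drop_values", values = "excluded")
  )
  p <- file.path(d, "filters.tsv")
  write_filter_spec(steps, p)
  back <- read_filter_spec(p)
  expect_length(back, 3)
  expect_equal(back[[1]]$values, c("case", "control"))
  expect_equal(back[[2]]$threshold, 18.5)
  expect_equal(back[[2]]$operator, ">=")
  expect_equal(back[[3]]$mode, "drop_values")
  expect_equal(back[[1]]$na_policy, "drop")
})

test_that("sequential filtering equals one pass over row predicates", {
  set.seed(505)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    tab <- data.frame(
      g = sample(c("a", "b", "c", NA), n, replace = TRUE),
      v = sample(c(as.character(1:9), NA), n, replace = TRUE),
      stringsAsFactors = FALSE)
    steps <- list(
      filter_step("g", "drop_values", values = "c",
                  na_policy = sample(c("keep", "drop"), 1)),
      filter_step("v", "numeric", operator = "<=", threshold = 6,
                  na_policy = sample(c("keep", "drop"), 1)))
    res <- filter_metadata(tab, steps)
    # oracle: conjunction of per-row predicates
    keep1 <- ifelse(is.na(tab$g), steps[[1]]$na_policy == "keep", tab$g != "c")
    keep2 <- ifelse(is.na(tab$v), steps[[2]]$na_policy == "keep",
                    as.numeric(tab$v) <= 6)
    expect_equal(res$table$g, tab$g[keep1 & keep2])
    expect_equal(res$report$rows_after[2], sum(keep1 & keep2))
    expect_equal(res$report$rows_after[1], res$report$rows_before[2])
  }
})
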