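write_fastq <- function(path, n_records, tag = "r") {
  con <- gzfile(path, "wb")
  for (i in seq_len(n_records)) {
    writeLines(c(sprintf("@%s.%d", tag, i), "ACGTACGT", "+", "IIIIIIII"),
               con, sep = "\n")
  }
  close(con)
  path
}

paired_dataset_dir <- function() {
  d <- tmp_dir()
  for (f in c("r1_1.fastq.gz", "r1_2.fastq.gz", "r2_1.fastq.gz",
              "r2_2.fastq.gz")) {
    write_fastq(file.path(d, f), 3, tag = f)
  }
  d
}

test_that("read side is inferred from common basename suffixes", {
  expect_equal(infer_read_side("a_1.fastq.gz"), "R1")
  expect_equal(infer_read_side("a_R2.fq.gz"), "R2")
  expect_equal(infer_read_side("a.2.fastq"), "R2")
  expect_true(is.na(infer_read_side("a.fastq.gz")))
})

test_that("multi-run paired samples plan one merge row per read side", {
  d <- paired_dataset_dir()
  tab <- ena_table(c("r1", "r2"), sample = "S", layout = "PAIRED",
                   fastq = c("h/r1_1.fastq.gz;h/r1_2.fastq.gz",
                             "h/r2_1.fastq.gz;h/r2_2.fastq.gz"))
  res <- make_treatment_template(tab, directory_inventory(d))
  t <- res$template
  expect_equal(nrow(t), 2)
  expect_equal(t$operation, c("merge", "merge"))
  expect_equal(t$read_side, c("R1", "R2"))
  expect_equal(t$input_files[1], "r1_1.fastq.gz;r2_1.fastq.gz") # run order
  expect_equal(t$output_file, c("S_1.fastq.gz", "S_2.fastq.gz"))
  expect_length(res$findings, 0)
})

test_that("canonical single-run files become copy rows, others rename", {
  d <- tmp_dir()
  write_fastq(file.path(d, "T.fastq.gz"), 2)
  write_fastq(file.path(d, "runX.fastq.gz"), 2)
  tab <- ena_table(c("rT", "rU"), sample = c("T", "U"), layout = "SINGLE",
                   fastq = c("h/T.fastq.gz", "h/runX.fastq.gz"))
  t <- make_treatment_template(tab, directory_inventory(d))$template
  expect_equal(t$operation[t$sample_name == "T"], "copy")
  expect_equal(t$output_file[t$sample_name == "T"], "T.fastq.gz")
  expect_equal(t$operation[t$sample_name == "U"], "rename")
  expect_equal(t$output_file[t$sample_name == "U"], "U.fastq.gz")
})

test_that("orphan files get a blank-sample row plus a warning", {
  d <- tmp_dir()
  write_fastq(file.path(d, "T.fastq.gz"), 1)
  write_fastq(file.path(d, "x.fq.gz"), 1)
  tab <- ena_table("rT", sample = "T", layout = "SINGLE",
                   fastq = "h/T.fastq.gz")
  res <- make_treatment_template(tab, directory_inventory(d))
  expect_equal(finding_codes(res$findings), "ORPHAN_FILE")
  orphan <- res$template[is.na(res$template$sample_name), ]
  expect_equal(orphan$input_files, "x.fq.gz")
  expect_true(is.na(orphan$operation))
})

test_that("template validation gates the executors", {
  d <- paired_dataset_dir()
  inv <- directory_inventory(d)
  good <- data.frame(sample_name = "S", operation = "merge",
                     input_files = "r1_1.fastq.gz;r2_1.fastq.gz",
                     read_side = "R1", output_file = "S_1.fastq.gz",
                     stringsAsFactors = FALSE)
  expect_length(validate_treatment_template(good, inv), 0)

  bad <- rbind(good,
               data.frame(sample_name = "S", operation = "copy",
                          input_files = "ghost.fastq.gz", read_side = "R1",
                          output_file = "ghost.fastq.gz"),
               data.frame(sample_name = "S", operation = "copy",
                          input_files = "r1_1.fastq.gz", read_side = "R1",
                          output_file = "S_1.fastq.gz"),
               data.frame(sample_name = "S", operation = "merge",
                          input_files = "r2_2.fastq.gz", read_side = "R2",
                          output_file = "S_2.fastq.gz"),
               data.frame(sample_name = NA, operation = NA,
                          input_files = "r1_2.fastq.gz", read_side = NA,
                          output_file = NA))
  codes <- finding_codes(validate_treatment_template(bad, inv))
  expect_setequal(codes, c("TEMPLATE_UNKNOWN_INPUT", "TEMPLATE_DUPLICATE_INPUT",
                           "TEMPLATE_DUPLICATE_OUTPUT", "TEMPLATE_BAD_ARITY",
                           "TEMPLATE_BLANK_FIELD"))
  expect_error(treat_fastqs(bad, d, tmp_dir()), "not executable")
})

test_that("merge concatenates gzipped records and conserves read counts", {
  d <- tmp_dir()
  write_fastq(file.path(d, "a_1.fastq.gz"), 4, tag = "a")
  write_fastq(file.path(d, "b_1.fastq.gz"), 6, tag = "b")
  template <- data.frame(sample_name = "S", operation = "merge",
                         input_files = "a_1.fastq.gz;b_1.fastq.gz",
                         read_side = "R1", output_file = "S_1.fastq.gz",
                         stringsAsFactors = FALSE)
  out <- tmp_dir()
  treat_fastqs(template, d, out)
  lines <- readLines(gzfile(file.path(out, "S_1.fastq.gz")))
  expect_equal(length(lines), 40) # 10 records x 4 lines
  expect_equal(length(lines) %% 4, 0)
  first <- readLines(gzfile(file.path(d, "a_1.fastq.gz")))
  expect_identical(lines[seq_along(first)], first)
})

test_that("copy and rename preserve bytes and are idempotent with overwrite", {
  d <- tmp_dir()
  write_fastq(file.path(d, "S.fastq.gz"), 3)
  write_fastq(file.path(d, "r1_1.fastq.gz"), 3)
  template <- data.frame(
    sample_name = c("S", "Q"), operation = c("copy", "rename"),
    input_files = c("S.fastq.gz", "r1_1.fastq.gz"),
    read_side = c("single", "R1"),
    output_file = c("S.fastq.gz", "Q_1.fastq.gz"),
    stringsAsFactors = FALSE)
  out <- tmp_dir()
  rep <- treat_fastqs(template, d, out)
  expect_equal(nrow(rep), 2)
  expect_equal(unname(tools::md5sum(file.path(out, "S.fastq.gz"))),
               unname(tools::md5sum(file.path(d, "S.fastq.gz"))))
  expect_equal(unname(tools::md5sum(file.path(out, "Q_1.fastq.gz"))),
               unname(tools::md5sum(file.path(d, "r1_1.fastq.gz"))))

  expect_error(treat_fastqs(template, d, out), "already exists")
  before <- tools::md5sum(file.path(out, c("S.fastq.gz", "Q_1.fastq.gz")))
  treat_fastqs(template, d, out, overwrite = TRUE)
  after <- tools::md5sum(file.path(out, c("S.fastq.gz", "Q_1.fastq.gz")))
  expect_identical(unname(before), unname(after))
  expect_error(treat_fastqs(template, d, d), "must differ")
})

test_that("metadata consolidation keeps agreements and flags conflicts", {
  tab <- ena_table(c("r1", "r2", "r3"), sample = c("S", "S", "T"),
                   host_age = c("34", "34", "60"),
                   host_sex = c("male", "female", "male"))
  template <- data.frame(
    sample_name = c("S", "T"), operation = c("merge", "copy"),
    input_files = c("r1.fastq.gz;r2.fastq.gz", "T.fastq.gz"),
    read_side = "single",
    output_file = c("S.fastq.gz", "T.fastq.gz"), stringsAsFactors = FALSE)
  res <- treat_metadata(template, tab)
  expect_equal(nrow(res$table), 2) # one row per template sample
  s_row <- res$table[res$table$sample_accession == "S", ]
  expect_equal(s_row$host_age, "34") # agreement kept, no warning
  expect_equal(s_row$host_sex, "male;female") # run order join
  expect_equal(s_row$run_accession, "r1;r2") # run-specific, silent
  expect_equal(res$report$column, "host_sex")
  expect_equal(res$report$sample, "S")
  expect_equal(finding_codes(res$findings), "SAMPLE_VALUE_CONFLICT")

  ghost <- rbind(template,
                 data.frame(sample_name = "Z", operation = "copy",
                            input_files = "z.fastq.gz", read_side = "single",
                            output_file = "Z.fastq.gz"))
  res <- treat_metadata(ghost, tab)
  expect_true("TEMPLATE_SAMPLE_UNMATCHED" %in% finding_codes(res$findings))
  expect_equal(nrow(res$table), 2)
})
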