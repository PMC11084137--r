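# Shared test fixtures: tiny ENA-style tables built in code, a fresh
# scratch directory per test, and independent brute-force oracles.

tmp_dir <- function() {
  d <- tempfile("scur_")
  dir.create(d)
  d
}

# minimal ena-dialect table; extra named arguments become extra columns
ena_table <- function(run, sample = paste0("S", seq_along(run)),
                      layout = "SINGLE",
                      fastq = paste0(run, ".fastq.gz"),
                      md5 = NA_character_,
                      submitted = NA_character_, ...) {
  n <- length(run)
  df <- data.frame(
    run_accession = run,
    sample_accession = rep_len(sample, n),
    library_layout = rep_len(layout, n),
    fastq_ftp = rep_len(fastq, n),
    fastq_md5 = rep_len(md5, n),
    scientific_name = rep_len("human gut metagenome", n),
    tax_id = rep_len("408170", n),
    instrument_platform = rep_len("ILLUMINA", n),
    instrument_model = rep_len("Illumina MiSeq", n),
    library_strategy = rep_len("WGS", n),
    library_source = rep_len("METAGENOMIC", n),
    submitted_ftp = rep_len(submitted, n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  attr(df, "dialect") <- "ena"
  df
}

rand_token <- function(n = 1, len = 6) {
  vapply(seq_len(n), function(i)
    paste(sample(c(letters, 0:9), len, replace = TRUE), collapse = ""), "")
}

# random generic table with some missing cells; cell values never collide
# with the missing-value token set
random_table <- function(nrow = 5, ncol = 3, na_frac = 0.15) {
  cols <- lapply(seq_len(ncol), function(j) {
    v <- rand_token(nrow)
    v[stats::runif(nrow) < na_frac] <- NA_character_
    v
  })
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  names(df) <- paste0("col_", seq_len(ncol))
  df
}

# brute-force row-pair oracle for the relational join semantics
join_oracle_nrow <- function(mk, ek, mode) {
  m <- vapply(mk, function(k) if (is.na(k)) 0L else sum(!is.na(ek) & ek == k),
              0L)
  e <- vapply(ek, function(k) if (is.na(k)) 0L else sum(!is.na(mk) & mk == k),
              0L)
  switch(mode,
         left = sum(pmax(m, 1L)),
         inner = sum(m),
         right = sum(pmax(e, 1L)),
         outer = sum(pmax(m, 1L)) + sum(e == 0L))
}

finding_codes <- function(findings, severities = c("warning", "error")) {
  tab <- findings_table(findings)
  sort(unique(tab$code[tab$severity %in% severities]))
}

# fast small synthetic dataset for integration-style tests
tiny_dataset <- function(seed, dir = tmp_dir(), n_samples = 4,
                         runs_per_sample = c(`1` = 0.5, `2` = 0.5),
                         layout_mix = 0.5, url_base = NULL) {
  generate_dataset(
    fixture_config(seed = seed, n_samples = n_samples,
                   runs_per_sample = runs_per_sample,
                   layout_mix = layout_mix,
                   reads_per_file = 5, read_length = 40,
                   url_base = url_base),
    dir)
}

# reference MD5 through an implementation independent of the package
# (Python hashlib); returns named vector basename -> digest
python_md5 <- function(paths) {
  script <- paste0(
    "import hashlib,sys\n",
    "for p in sys.argv[1:]:\n",
    "    print(hashlib.md5(open(p,'rb').read()).hexdigest())")
  out <- system2("python", c("-c", shQuote(script), shQuote(paths)),
                 stdout = TRUE)
  stats::setNames(out, basename(paths))
}
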