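# Synthetic-dataset generator and defect injector: ENA-like run-level
# metadata, matching gzipped FASTQ files with true MD5 digests, a
# manifest and a variables dictionary, so that every check of the
# workflow is testable offline. Reads are uniform-random ACGT with
# constant quality; biological realism is irrelevant to file-level
# curation.

#' Configuration of the synthetic dataset generator
#'
#' @param seed Integer seed; identical (config, seed) gives byte-identical
#'   outputs.
#' @param n_samples Number of biological samples.
#' @param runs_per_sample Named probability vector over run counts
#'   `"1"`, `"2"`, `"3"`.
#' @param layout_mix Proportion of samples with PAIRED layout (layout is
#'   a property of the sample; all its runs share it).
#' @param reads_per_file Fastq records per file.
#' @param read_length Bases per read.
#' @param attribute_schema List of attribute descriptors, each a list
#'   with `name`, `kind` (`"categorical"`, `"numeric"` or `"freetext"`)
#'   and `pool` (categorical/freetext value pool) or `range`
#'   (numeric `c(min, max)` integer range). Attributes are constant
#'   within a sample.
#' @param url_base Base URL recorded in `fastq_ftp`/`submitted_ftp`;
#'   `NULL` (default) uses `file://<out_dir>/fastqs` so the files can be
#'   re-downloaded locally.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_samples = 6L,
                           runs_per_sample = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                           layout_mix = 0.5,
                           reads_per_file = 25L,
                           read_length = 75L,
                           attribute_schema = default_attribute_schema(),
                           url_base = NULL) {
  stopifnot(n_samples >= 1, reads_per_file >= 1, read_length >= 1,
            layout_mix >= 0, layout_mix <= 1,
            all(runs_per_sample >= 0), sum(runs_per_sample) > 0,
            all(names(runs_per_sample) %in% c("1", "2", "3")))
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 runs_per_sample = runs_per_sample / sum(runs_per_sample),
                 layout_mix = layout_mix,
                 reads_per_file = as.integer(reads_per_file),
                 read_length = as.integer(read_length),
                 attribute_schema = attribute_schema,
                 url_base = url_base),
            class = "fixture_config")
}

#' Default sample-attribute schema of the generator
#'
#' Three attributes typical of host-associated studies: a categorical
#' host sex, a numeric host age (years) and a free-text geographic
#' origin.
#'
#' @return List of attribute descriptors.
#' @export
default_attribute_schema <- function() {
  list(
    list(name = "host_sex", kind = "categorical", pool = c("female", "male")),
    list(name = "host_age", kind = "numeric", range = c(18, 90)),
    list(name = "geo_location", kind = "freetext",
         pool = c("France", "Italy", "Portugal", "Spain"))
  )
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_fastq_gz <- function(path, run, n_reads, read_len, mate = NULL) {
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(n_reads)) {
    id <- if (is.null(mate)) sprintf("@%s.%d", run, i) else
      sprintf("@%s.%d/%s", run, i, mate)
    writeLines(c(id, random_read(read_len), "+",
                 strrep("I", read_len)), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Generate a synthetic ENA-like dataset
#'
#' Writes, under `out_dir`: `fastqs/` with gzipped FASTQ files,
#' `metadata.tsv` (ena dialect; `fastq_md5` cells hold the true digests
#' of the generated files), `manifest.tsv` and `dictionary.tsv`.
#' Accessions are synthetic (runs `ERR` + 7 digits, samples `SAMEA` + 8
#' digits). Output is deterministic given the config.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if absent).
#' @return Object of class `fixture_dataset`: list with `dir`, `config`,
#'   `metadata`, `manifest`, `dictionary`, `inventory` and `paths`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fq_dir <- file.path(out_dir, "fastqs")
  if (!dir.exists(fq_dir)) dir.create(fq_dir)
  url_base <- if (is.null(config$url_base)) {
    paste0("file://", normalizePath(fq_dir, winslash = "/"))
  } else config$url_base

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  run_counter <- 1000000L + sample.int(1000000L, 1)
  sample_base <- 10000000L + sample.int(10000000L, 1)
  platforms <- list(c("ILLUMINA", "Illumina MiSeq"),
                    c("ILLUMINA", "Illumina NovaSeq 6000"))
  datatypes <- list(c("AMPLICON", "METAGENOMIC"), c("WGS", "METAGENOMIC"))

  rows <- list()
  manifest_rows <- list()
  for (s in seq_len(config$n_samples)) {
    sample_acc <- sprintf("SAMEA%08d", sample_base + s)
    sample_alias <- sprintf("sample_%02d", s)
    n_runs <- as.integer(sample(names(config$runs_per_sample), 1,
                                prob = config$runs_per_sample))
    layout <- if (stats::runif(1) < config$layout_mix) "PAIRED" else "SINGLE"
    platform <- platforms[[sample(length(platforms), 1)]]
    datatype <- datatypes[[sample(length(datatypes), 1)]]
    organism <- c("human gut metagenome", "408170")
    attrs <- lapply(config$attribute_schema, function(a) {
      switch(a$kind,
             categorical = ,
             freetext = sample(a$pool, 1),
             numeric = as.character(sample(seq(a$range[1], a$range[2]), 1)))
    })
    for (r in seq_len(n_runs)) {
      run <- sprintf("ERR%07d", run_counter)
      run_counter <- run_counter + 1L
      files <- if (layout == "PAIRED") {
        paste0(run, c("_1", "_2"), ".fastq.gz")
      } else paste0(run, ".fastq.gz")
      for (k in seq_along(files)) {
        write_fastq_gz(file.path(fq_dir, files[k]), run,
                       config$reads_per_file, config$read_length,
                       mate = if (layout == "PAIRED") k else NULL)
      }
      digests <- unname(tools::md5sum(file.path(fq_dir, files)))
      submitted <- sub("\\.fastq\\.gz$", "_raw.fq.gz", files)
      row <- list(
        run_accession = run,
        sample_accession = sample_acc,
        sample_alias = sample_alias,
        library_layout = layout,
        fastq_ftp = paste(paste(url_base, files, sep = "/"), collapse = ";"),
        fastq_md5 = paste(digests, collapse = ";"),
        scientific_name = organism[1],
        tax_id = organism[2],
        instrument_platform = platform[1],
        instrument_model = platform[2],
        library_strategy = datatype[1],
        library_source = datatype[2],
        submitted_ftp = paste(paste(url_base, submitted, sep = "/"),
                              collapse = ";"),
        submitted_md5 = paste(digests, collapse = ";")
      )
      for (j in seq_along(config$attribute_schema)) {
        row[[config$attribute_schema[[j]]$name]] <- attrs[[j]]
      }
      rows[[length(rows) + 1]] <- row
      for (f in files) {
        manifest_rows[[length(manifest_rows) + 1]] <-
          list(fastq_file_name = f, sample_name = sample_acc,
               md5 = unname(tools::md5sum(file.path(fq_dir, f))))
      }
    }
  }
  metadata <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  manifest <- do.call(rbind, lapply(manifest_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  dictionary <- fixture_dictionary(config, names(metadata))

  paths <- list(metadata = file.path(out_dir, "metadata.tsv"),
                manifest = file.path(out_dir, "manifest.tsv"),
                dictionary = file.path(out_dir, "dictionary.tsv"),
                fastq_dir = fq_dir)
  write_metadata_table(metadata, paths$metadata)
  write_metadata_table(manifest, paths$manifest)
  write_variables_dictionary(dictionary, paths$dictionary)
  structure(list(dir = out_dir, config = config, metadata = metadata,
                 manifest = manifest, dictionary = dictionary,
                 inventory = directory_inventory(fq_dir), paths = paths),
            class = "fixture_dataset")
}

# run-level dictionary covering every generated column
fixture_dictionary <- function(config, columns) {
  specs <- list(
    variable_spec("run_accession", "required", "character", "unique"),
    variable_spec("sample_accession", "required", "character", "nonunique",
                  crosscheck_variables = "sample_alias"),
    variable_spec("sample_alias", "required", "character", "nonunique"),
    variable_spec("library_layout", "required", "character", "nonunique",
                  allowed_analysis = "subset",
                  allowed_values = c("PAIRED", "SINGLE")),
    variable_spec("fastq_ftp", "required", "character", "unique"),
    variable_spec("fastq_md5", "required", "character", "nonunique"),
    variable_spec("scientific_name", "required", "character", "nonunique"),
    variable_spec("tax_id", "required", "numeric", "nonunique"),
    variable_spec("instrument_platform", "optional", "character", "nonunique"),
    variable_spec("instrument_model", "optional", "character", "nonunique"),
    variable_spec("library_strategy", "optional", "character", "nonunique"),
    variable_spec("library_source", "optional", "character", "nonunique"),
    variable_spec("submitted_ftp", "optional", "character", "nonunique"),
    variable_spec("submitted_md5", "optional", "character", "nonunique")
  )
  for (a in config$attribute_schema) {
    specs[[length(specs) + 1]] <- switch(a$kind,
      categorical = variable_spec(a$name, "optional", "character", "nonunique",
                                  allowed_analysis = "subset",
                                  allowed_values = a$pool),
      numeric = variable_spec(a$name, "optional", "numeric", "nonunique",
                              allowed_analysis = "range",
                              allowed_values = a$range),
      freetext = variable_spec(a$name, "optional", "character", "nonunique"))
  }
  new_variables_dictionary(specs)
}

#' @export
print.fixture_dataset <- function(x, ...) {
  cat(sprintf("<synthetic dataset: %d run(s), %d fastq file(s) in %s>\n",
              nrow(x$metadata), length(x$inventory$files), x$dir))
  invisible(x)
}

.defect_codes <- c("DELETE_FILE", "EXTRA_FILE", "CORRUPT_FILE", "WRONG_MD5",
                   "PAIRED_MISSING_MATE", "DUP_SUBMITTED_NAME",
                   "SAMPLE_LAYOUT_CONFLICT", "SAMPLE_ORGANISM_CONFLICT",
                   "REQUIRED_VAR_DROPPED", "VALUE_OUT_OF_RANGE",
                   "DUP_UNIQUE_ID_ACROSS_DATASETS", "CONFLICTING_SAMPLE_VALUES")

#' Mapping of injectable defects to expected finding codes
#'
#' Documents, for every defect the injector can realize, which check
#' program is designated to detect it and which finding code that check
#' must emit.
#'
#' @return Data frame with columns `defect`, `check`, `finding_code`.
#' @export
defect_check_map <- function() {
  data.frame(
    defect = .defect_codes,
    check = c("check-fastqs", "check-fastqs", "check-fastqs", "check-fastqs",
              "check-metadata-ena", "check-metadata-ena",
              "check-metadata-ena", "check-metadata-ena",
              "check-metadata-values", "check-metadata-values",
              "concat-datasets", "treat-metadata"),
    finding_code = c("MISSING_FILE", "UNEXPECTED_FILE", "MD5_MISMATCH",
                     "MD5_MISMATCH", "LAYOUT_FILECOUNT_MISMATCH",
                     "DUPLICATED_SUBMITTED_NAME", "SAMPLE_MULTIMATCH_LAYOUT",
                     "SAMPLE_MULTIMATCH_ORGANISM", "VARIABLE_MISSING",
                     "VALUE_OUT_OF_RANGE", "CROSS_DATASET_DUPLICATE",
                     "SAMPLE_VALUE_CONFLICT"),
    stringsAsFactors = FALSE
  )
}

pick <- function(eligible, rng_seed) {
  if (!length(eligible)) return(NULL)
  eligible[1 + (rng_seed %% length(eligible))]
}

# rewrite the dataset's mutated tables to disk so file-based workflows
# see the same defect as in-memory ones
flush_dataset <- function(dataset) {
  write_metadata_table(dataset$metadata, dataset$paths$metadata)
  write_metadata_table(dataset$manifest, dataset$paths$manifest)
  dataset$inventory <- directory_inventory(dataset$paths$fastq_dir)
  dataset
}

#' Inject a single defect into a generated dataset
#'
#' Applies exactly one minimal mutation realizing the requested defect
#' and returns both the mutated dataset and the expectation: which
#' finding code, on which subject, the designated check must now emit
#' (see [defect_check_map()]).
#'
#' @param dataset A `fixture_dataset` from [generate_dataset()].
#' @param defect One of the codes in [defect_check_map()].
#' @param rng_seed Integer choosing the victim among the eligible
#'   entities (deterministically).
#' @param second A second `fixture_dataset`, required by
#'   `DUP_UNIQUE_ID_ACROSS_DATASETS`.
#' @param attribute Attribute column targeted by
#'   `CONFLICTING_SAMPLE_VALUES`; default the first schema attribute.
#' @return List with `dataset` (mutated) and `expectation` (list with
#'   `check`, `code`, `subject`).
#' @export
inject_defect <- function(dataset, defect, rng_seed = 0L, second = NULL,
                          attribute = NULL) {
  stopifnot(inherits(dataset, "fixture_dataset"))
  if (!defect %in% .defect_codes) stop("unknown defect: ", defect, call. = FALSE)
  md <- dataset$metadata
  map <- defect_check_map()
  expect_code <- map$finding_code[map$defect == defect]
  expect_check <- map$check[map$defect == defect]
  subject <- NULL

  if (defect == "DELETE_FILE") {
    f <- pick(dataset$inventory$files, rng_seed)
    file.remove(file.path(dataset$paths$fastq_dir, f))
    subject <- f
  } else if (defect == "EXTRA_FILE") {
    f <- "unexpected_extra.fastq.gz"
    write_fastq_gz(file.path(dataset$paths$fastq_dir, f), "EXTRA", 1, 10)
    subject <- f
  } else if (defect == "CORRUPT_FILE") {
    f <- pick(dataset$inventory$files, rng_seed)
    path <- file.path(dataset$paths$fastq_dir, f)
    bytes <- readBin(path, "raw", n = file.size(path))
    i <- length(bytes) %/% 2 + 1L
    bytes[i] <- xor(bytes[i], as.raw(1L)) # single bit flip
    writeBin(bytes, path)
    subject <- f
  } else if (defect == "WRONG_MD5") {
    i <- pick(seq_len(nrow(md)), rng_seed)
    digests <- split_multivalue(md$fastq_md5[i])
    d <- digests[1]
    first <- substr(d, 1, 1)
    substr(d, 1, 1) <- if (first == "0") "1" else "0"
    digests[1] <- d
    md$fastq_md5[i] <- paste(digests, collapse = ";")
    subject <- url_basename(split_multivalue(md$fastq_ftp[i])[1])
  } else if (defect == "PAIRED_MISSING_MATE") {
    eligible <- which(md$library_layout == "PAIRED")
    if (!length(eligible)) stop("defect inapplicable: no PAIRED runs", call. = FALSE)
    i <- pick(eligible, rng_seed)
    md$fastq_ftp[i] <- split_multivalue(md$fastq_ftp[i])[1]
    md$fastq_md5[i] <- split_multivalue(md$fastq_md5[i])[1]
    subject <- md$run_accession[i]
  } else if (defect == "DUP_SUBMITTED_NAME") {
    if (nrow(md) < 2) stop("defect inapplicable: need two runs", call. = FALSE)
    i <- pick(seq_len(nrow(md) - 1), rng_seed)
    donor <- split_multivalue(md$submitted_ftp[i])[1]
    victim <- split_multivalue(md$submitted_ftp[i + 1])
    victim[1] <- paste(c(head_dir(victim[1]), url_basename(donor)), collapse = "/")
    md$submitted_ftp[i + 1] <- paste(victim, collapse = ";")
    subject <- url_basename(donor)
  } else if (defect == "SAMPLE_LAYOUT_CONFLICT") {
    multi <- names(which(table(md$sample_accession) > 1))
    eligible <- which(md$sample_accession %in% multi & md$library_layout == "PAIRED")
    if (!length(eligible)) {
      stop("defect inapplicable: no multi-run PAIRED sample", call. = FALSE)
    }
    i <- pick(eligible, rng_seed)
    md$library_layout[i] <- "SINGLE"
    # keep the layout/file-count rule satisfied so only the per-sample
    # conflict fires
    md$fastq_ftp[i] <- split_multivalue(md$fastq_ftp[i])[1]
    md$fastq_md5[i] <- split_multivalue(md$fastq_md5[i])[1]
    subject <- md$sample_accession[i]
  } else if (defect == "SAMPLE_ORGANISM_CONFLICT") {
    multi <- names(which(table(md$sample_accession) > 1))
    if (!length(multi)) stop("defect inapplicable: no multi-run sample", call. = FALSE)
    i <- pick(which(md$sample_accession %in% multi), rng_seed)
    md$scientific_name[i] <- "human skin metagenome"
    md$tax_id[i] <- "539655"
    subject <- md$sample_accession[i]
  } else if (defect == "REQUIRED_VAR_DROPPED") {
    md$scientific_name <- NULL
    subject <- "scientific_name"
  } else if (defect == "VALUE_OUT_OF_RANGE") {
    numeric_attrs <- Filter(function(a) a$kind == "numeric",
                            dataset$config$attribute_schema)
    if (!length(numeric_attrs)) {
      stop("defect inapplicable: no numeric attribute", call. = FALSE)
    }
    a <- numeric_attrs[[1]]
    i <- pick(seq_len(nrow(md)), rng_seed)
    bad <- as.character(a$range[2] + 44)
    md[[a$name]][i] <- bad
    subject <- bad
  } else if (defect == "DUP_UNIQUE_ID_ACROSS_DATASETS") {
    if (is.null(second)) {
      stop("DUP_UNIQUE_ID_ACROSS_DATASETS needs a second dataset", call. = FALSE)
    }
    i <- pick(seq_len(nrow(md)), rng_seed)
    donor <- second$metadata$run_accession[1]
    md$run_accession[i] <- donor
    subject <- donor
  } else if (defect == "CONFLICTING_SAMPLE_VALUES") {
    multi <- names(which(table(md$sample_accession) > 1))
    if (!length(multi)) stop("defect inapplicable: no multi-run sample", call. = FALSE)
    if (is.null(attribute)) attribute <- dataset$config$attribute_schema[[1]]$name
    a <- Filter(function(x) x$name == attribute, dataset$config$attribute_schema)[[1]]
    i <- pick(which(md$sample_accession %in% multi), rng_seed)
    cur <- md[[attribute]][i]
    md[[attribute]][i] <- if (a$kind == "numeric") {
      as.character(as.numeric(cur) + 1)
    } else setdiff(a$pool, cur)[1]
    subject <- md$sample_accession[i]
  }

  dataset$metadata <- md
  dataset <- flush_dataset(dataset)
  list(dataset = dataset,
       expectation = list(check = expect_check, code = expect_code,
                          subject = subject))
}

head_dir <- function(url) sub("/[^/]*$", "", url)
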