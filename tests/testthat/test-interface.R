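write_lines <- function(lines, path) writeLines(lines, path)

test_that("count matrices round-trip through TSV and GCT identically", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "counts.tsv")
  write_lines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4", "g3\t5\t6"), tsv)
  m <- read_counts(tsv)
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(m["g2", "s2"], 4L)

  gct <- file.path(dir, "counts.gct")
  write_lines(c("#1.2", "3\t2", "Name\tDescription\ts1\ts2",
                "g1\tdesc\t1\t2", "g2\tdesc\t3\t4", "g3\tdesc\t5\t6"), gct)
  expect_identical(read_counts(gct), m)

  bad_dims <- file.path(dir, "bad.gct")
  write_lines(c("#1.2", "5\t2", "Name\tDescription\ts1\ts2",
                "g1\tdesc\t1\t2"), bad_dims)
  expect_error(read_counts(bad_dims), "dimensions")
})

test_that("count validation rejects duplicates and non-integers", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  write_lines(c("gene\ts1", "g1\t1", "g1\t2"), dup)
  expect_error(read_counts(dup), "duplicate gene")

  frac <- file.path(dir, "frac.tsv")
  write_lines(c("gene\ts1\ts2", "g1\t1.5\t2"), frac)
  expect_error(read_counts(frac), "non-integer count at gene 'g1'")

  neg <- file.path(dir, "neg.tsv")
  write_lines(c("gene\ts1", "g1\t-3"), neg)
  expect_error(read_counts(neg), "nonnegative")
})

test_that("copy-number reader tolerates annotation columns and NA cells", {
  dir <- withr::local_tempdir()
  cn <- file.path(dir, "cn.tsv")
  write_lines(c("gene\tsymbol\tcytoband\ts1\ts2",
                "g1\tTP53\t17p13\t0\t1",
                "g2\tMYC\t8q24\tNA\t0.5"), cn)
  m <- read_copy_number(cn)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g1", "s2"], 1)
  expect_true(is.na(m["g2", "s1"]))
  ann <- attr(m, "annotations")
  expect_equal(ann$symbol, c("TP53", "MYC"))
  # the NA cell is flagged missing by the encoder
  expect_true(encode_copy_number(m)$missing["g2", "s1"])
})

test_that("sample metadata defaults purity with a warning for tumors", {
  dir <- withr::local_tempdir()
  meta <- file.path(dir, "meta.tsv")
  write_lines(c("sample_id\ttissue", "s1\tlung", "s2\tlung"), meta)
  expect_warning(info <- read_sample_info(meta, "tumor"), "purity")
  expect_equal(info$purity, c(1, 1))
  expect_silent(read_sample_info(meta, "cellline"))
  expect_error(read_sample_info(meta, "tumor2"))
})

test_that("ORF reader computes lfc from counts and rejects duplicates", {
  dir <- withr::local_tempdir()
  orf <- file.path(dir, "orf.tsv")
  write_lines(c("screen\ttissue\tbarcode\tgene\tearly_count\tlate_count",
                "s1\tlung\tb1\tg1\t100\t50",
                "s1\tlung\tb2\tg2\t100\t100"), orf)
  obs <- read_orf_screens(orf)
  expect_equal(obs$lfc,
               compute_barcode_lfc(c(100, 100), c(50, 100)),
               tolerance = 1e-12)

  dup <- file.path(dir, "dup_orf.tsv")
  write_lines(c("screen\ttissue\tbarcode\tgene\tlfc",
                "s1\tlung\tb1\tg1\t-1", "s1\tlung\tb1\tg1\t-2"), dup)
  expect_error(read_orf_screens(dup), "duplicate")
})

test_that("the file pipeline runs end to end and reruns byte-identically", {
  dir <- withr::local_tempdir()
  fx <- small_cohort_fixture(dir, seed = 77, samples = 60)
  membership <- data.frame(complex_id = "cpx1", gene = c("COMP1", "SCAL1"))
  write.table(membership, file.path(dir, "complexes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- pipeline_config(
    counts_a = file.path(dir, "counts.tsv"),
    copy_a = file.path(dir, "copy_number.tsv"),
    meta_a = file.path(dir, "sample_info.tsv"),
    orf = file.path(dir, "orf_screens.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    chains = 2, iter = 500, warmup = 400, seed = 5
  )
  out1 <- file.path(dir, "out1")
  res <- run_pipeline(cfg, out1)
  produced <- list.files(out1)
  expect_setequal(produced, c("compensation.tsv", "toxicity.tsv",
                              "argos.tsv", "complexes.tsv",
                              "run_manifest.json"))

  # outputs parse back and the planted gene is recovered
  argos_tab <- read.delim(file.path(out1, "argos.tsv"))
  expect_true(argos_tab$argos[argos_tab$gene == "COMP1"])
  expect_false(any(argos_tab$argos[argos_tab$gene != "COMP1"]))
  comp_tab <- read.delim(file.path(out1, "compensation.tsv"))
  expect_true(all(c("gene", "score", "pseudo_p", "converged") %in%
                    names(comp_tab)))

  # byte-identical rerun under the same config and seed
  out2 <- file.path(dir, "out2")
  run_pipeline(cfg, out2)
  for (f in produced) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a YAML config resolves relative paths and drives the pipeline", {
  dir <- withr::local_tempdir()
  small_cohort_fixture(dir, seed = 78, samples = 50)
  yaml_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    counts_a = "counts.tsv", copy_a = "copy_number.tsv",
    meta_a = "sample_info.tsv", orf = "orf_screens.tsv",
    chains = 2L, iter = 200L, warmup = 150L, seed = 3L
  ), yaml_path)
  cfg <- read_pipeline_config(yaml_path)
  expect_true(file.exists(cfg$counts_a))
  res <- run_pipeline(cfg, file.path(dir, "out"))
  expect_s3_class(res$argos, "data.frame")
})
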