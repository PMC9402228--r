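test_that("maternal ratio uses non-rounded counts", {
  expect_equal(maternal_ratio(75, 25), 0.75)
  expect_equal(maternal_ratio(10, 0), 1.0)
  expect_equal(maternal_ratio(7.8, 2.3), 7.8 / 10.1)
  expect_error(maternal_ratio(0, 0), "undefined")
  # relabeling maternal/paternal mirrors the ratio exactly
  m <- c(3, 80.5, 0, 12)
  p <- c(9, 19.5, 7, 12)
  expect_equal(maternal_ratio(m, p), 1 - maternal_ratio(p, m))
})

test_that("TSV round trip preserves a validated table", {
  tab <- make_counts(c("g1", "g1", "g2", "g2"),
                     c("r1", "r2", "r1", "r2"),
                     c(10, 12.5, 0, 3), c(2, 0.5, 8, 3))
  path <- tempfile(fileext = ".tsv")
  write_allele_counts(tab, path)
  back <- read_allele_counts(path, assay = "rna")
  expect_equal(back$maternal_count, tab$maternal_count)
  expect_equal(back$gene_id, tab$gene_id)
})

test_that("malformed tables are rejected with informative errors", {
  tab <- make_counts("g1", "r1", -1, 5)
  expect_error(validate_allele_counts(tab), "negative")
  dup <- make_counts(c("g1", "g1"), c("r1", "r1"), c(1, 2), c(3, 4))
  expect_error(validate_allele_counts(dup), "g1")
  bad_assay <- make_counts("g1", "r1", 1, 2, assay = "chip")
  expect_error(validate_allele_counts(bad_assay), "assay")

  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\treplicate\tmaternal_count\tpaternal_count\tsample_role\tassay",
               "g1\tr1\tten\t2\tembryo\trna"), path)
  expect_error(read_allele_counts(path), "line 2")
  expect_error(read_allele_counts(tempfile(fileext = ".tsv")), "not found")
})

test_that("RNA depth filter keeps >= 50 reads summed over replicates", {
  tab <- make_counts(rep(c("g49", "g50"), each = 2),
                     rep(c("r1", "r2"), 2),
                     c(25, 14, 26, 14), c(0, 10, 0, 10))
  res <- apply_depth_filter(tab, "rna")
  expect_setequal(unique(res$kept$gene_id), "g50")
  expect_equal(res$dropped$gene_id, "g49")
})

test_that("CUT&RUN depth filter needs strictly more than 10 per replicate", {
  tab <- make_counts(rep(c("gA", "gB"), each = 2),
                     rep(c("r1", "r2"), 2),
                     c(9, 100, 10.5, 100), c(1, 50, 0.6, 50),
                     assay = "cutrun")
  res <- apply_depth_filter(tab, "cutrun")
  # gA has a replicate with exactly 10 total -> dropped; gB's minimum
  # replicate total is 11.1 -> kept
  expect_setequal(unique(res$kept$gene_id), "gB")
  expect_equal(res$dropped$gene_id, "gA")
})

test_that("depth filter is idempotent and partitions the gene set", {
  set.seed(77)
  tab <- make_counts(rep(sprintf("g%02d", 1:30), each = 3),
                     rep(c("r1", "r2", "r3"), 30),
                     rpois(90, 20), rpois(90, 5))
  res <- apply_depth_filter(tab, "rna")
  twice <- apply_depth_filter(res$kept, "rna")
  expect_identical(twice$kept, res$kept)
  expect_equal(nrow(twice$dropped), 0)
  expect_setequal(c(unique(res$kept$gene_id), res$dropped$gene_id),
                  unique(tab$gene_id))
})

test_that("parental-control exclusion honors the five-read qualifier", {
  embryo <- make_counts(rep(c("g1", "g2", "g3"), each = 2),
                        rep(c("r1", "r2"), 3),
                        rpois(6, 30) + 10, rpois(6, 5))
  # g1: impure maternal control with 10 reads -> excluded
  # g2: impure but only 4 reads -> kept
  # g3: perfect controls -> kept
  m_ctrl <- make_counts(c("g1", "g2", "g3"), "c1", c(9, 3, 20),
                        c(1, 1, 0), role = "maternal_control")
  p_ctrl <- make_counts(c("g1", "g2", "g3"), "c1", c(0, 0, 0),
                        c(50, 50, 50), role = "paternal_control")
  res <- apply_parental_control_filter(embryo, m_ctrl, p_ctrl)
  expect_equal(res$excluded$gene_id, "g1")
  expect_equal(res$excluded$reason, "maternal_control_impure")
  expect_setequal(unique(res$kept$gene_id), c("g2", "g3"))
})

test_that("paternal-control leakage above 0.05 excludes a gene", {
  embryo <- make_counts(c("g1", "g2"), "r1", c(40, 40), c(5, 5))
  p_ctrl <- make_counts(c("g1", "g2"), "c1", c(1, 0), c(9, 10),
                        role = "paternal_control")
  res <- apply_parental_control_filter(embryo,
                                       paternal_control = p_ctrl)
  expect_equal(res$excluded$gene_id, "g1")
  # genes absent from a control table are not excluded by it
  embryo2 <- make_counts("gX", "r1", 40, 5)
  res2 <- apply_parental_control_filter(embryo2, p_ctrl, p_ctrl)
  expect_equal(nrow(res2$excluded), 0)
})
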