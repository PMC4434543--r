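small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_genes = c(shared_up = 6, bcr_pref_up = 4, unchanged = 6),
             ...)
}

test_that("requested class sizes, strand balance and truth partition hold", {
  cfg <- sim_config(seed = 2, n_genes = c(shared_up = 50))
  ds <- generate_dataset(cfg, what = "expression")
  expect_equal(nrow(ds$genes), 50)
  expect_true(all(ds$truth$gene_class == "shared_up"))
  expect_equal(length(ds$truth$gene_class), 50)        # every gene once
  expect_true(!anyDuplicated(names(ds$truth$gene_class)))
  expect_lte(abs(sum(ds$genes$strand == "+") -
                   sum(ds$genes$strand == "-")), 1)
  # strand balance holds per class too
  cfg2 <- small_cfg()
  g2 <- generate_dataset(cfg2, what = "expression")$genes
  for (cl in unique(g2$class)) {
    s <- g2$strand[g2$class == cl]
    expect_lte(abs(sum(s == "+") - sum(s == "-")), 1)
  }
})

test_that("a fixed seed reproduces the dataset and its files byte for byte", {
  lib <- list(polII = c(rest = 2e5, BCR = 2e5, LPS = 2e5))
  ds1 <- generate_dataset(small_cfg(seed = 9, library_sizes = lib),
                          signals = "polII")
  ds2 <- generate_dataset(small_cfg(seed = 9, library_sizes = lib),
                          signals = "polII")
  expect_identical(ds1$annotation, ds2$annotation)
  expect_identical(ds1$expression, ds2$expression)
  expect_identical(as.character(ds1$genome), as.character(ds2$genome))
  expect_identical(ds1$tracks$polII$BCR$counts, ds2$tracks$polII$BCR$counts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("subsets of components reproduce the full-run draws", {
  full <- generate_dataset(small_cfg(seed = 4))
  only_mirna <- generate_dataset(small_cfg(seed = 4), what = "mirna")
  expect_identical(full$mirna, only_mirna$mirna)
})

test_that("mean coverage converges to the configured model", {
  lib <- list(polII = c(rest = 1.8e7, BCR = 1.8e7, LPS = 1.8e7))
  cfg <- sim_config(seed = 6, n_genes = c(shared_up = 40),
                    n_tss_range = c(1, 1), library_sizes = lib)
  ds <- generate_dataset(cfg, what = "coverage", signals = "polII")
  prof <- metagene_profile(ds$tracks$polII$rest, ds$annotation,
                           window = c(-2000, 2000))
  at <- function(off) prof$mean_rpm[off - prof$window[1] + 1]
  # peak apex: peak height + background
  expect_equal(at(0), cfg$promoter_peak_height + cfg$background_rpm,
               tolerance = 0.05)
  # gene body beyond the peak: body density + background
  body_pred <- cfg$body_density + cfg$background_rpm
  expect_equal(mean(vapply(1200:1800, at, numeric(1))), body_pred,
               tolerance = 0.05)
  # upstream of the TSS: background only
  expect_equal(mean(vapply(-2000:-1200, at, numeric(1))),
               cfg$background_rpm, tolerance = 0.05 * body_pred)
})

test_that("written bedGraph round-trips to the original per-base counts", {
  set.seed(31)
  vals <- rpois(4000, 0.8)
  tr <- make_track(vals, total_reads = 5e5)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, total_reads = 5e5,
                        chrom_lengths = c(chr1 = 4000))
  expect_equal(as.numeric(back$counts$chr1), as.numeric(vals))
})

test_that("annotation files carry strand and coordinate conventions", {
  cfg <- sim_config(seed = 3, n_genes = c(shared_up = 1),
                    n_tss_range = c(1, 1))
  ds <- generate_dataset(cfg, what = "expression")
  ds$genes$strand <- "-"
  ds$annotation$strand <- "-"
  ds$annotation$tss <- ds$annotation$end - 1L
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  bed <- read.delim(file.path(d, "annotation.bed"), header = FALSE)
  expect_equal(bed$V6[1], "-")
  expect_equal(bed$V2[1], ds$genes$start[1])      # BED is 0-based
  ann <- read_annotation(file.path(d, "annotation.gtf"))
  expect_equal(ann$start, ds$annotation$start)    # GTF is 1-based closed
  expect_equal(ann$tss, ds$annotation$tss)
})

test_that("an empty dataset writes headers-only tables", {
  cfg <- sim_config(seed = 1,
                    n_genes = stats::setNames(integer(0), character(0)))
  ds <- generate_dataset(cfg, what = c("expression", "mirna"))
  expect_equal(nrow(ds$annotation), 0)
  expect_equal(nrow(ds$expression), 0)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  expect_equal(readLines(file.path(d, "expression.tsv")),
               "gene_id\trest\tBCR30\tBCR120\tLPS30\tLPS120")
})

test_that("impossible geometry is a configuration error", {
  expect_error(sim_config(n_genes = c(a = 100), chrom_length = 1e5),
               "too small")
  expect_error(sim_config(flank = 1000), "flank")
  expect_error(sim_config(tss_jitter_range = c(0, 500)), "jitter")
})
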