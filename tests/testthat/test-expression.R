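test_that("fold_change applies the pseudocount and rejects bad input", {
  expect_equal(fold_change(10, 40, 1), 41 / 11)
  expect_equal(fold_change(c(0, 5, 123), c(0, 5, 123)), c(1, 1, 1))
  expect_equal(fold_change(0, 0, 1), 1)
  expect_error(fold_change(-1, 2), "non-negative")
  expect_error(fold_change(1, 2, pseudocount = 0), "pseudocount")
})

test_that("twofold calls are boundary-inclusive", {
  expect_equal(call_de(c(2, 1, 0.25, 1.99, 0.51)),
               c("up", "none", "down", "none", "none"))
  expect_equal(call_de(0.5), "down")
  expect_error(call_de(2, threshold = 1), "threshold")
  expect_error(call_de(0), "folds")
})

test_that("classify_gene implements the shared/preferential rule", {
  # induced side: single-response, banded preferential, shared
  expect_equal(classify_gene(8.0, 1.2, 50), "bcr_pref_up")
  expect_equal(classify_gene(8.0, 3.0, 50), "bcr_pref_up")   # 3 in [2,4], 8 >= 6
  expect_equal(classify_gene(3.0, 2.9, 50), "shared_up")     # 3 < 5.8
  expect_equal(classify_gene(3.0, 8.0, 50), "lps_pref_up")
  expect_equal(classify_gene(4.0, 4.0, 50), "shared_up")
  # reduced side mirrors on reciprocal folds
  expect_equal(classify_gene(0.2, 1.0, 50), "bcr_pref_down")
  expect_equal(classify_gene(1 / 8, 1 / 3, 50), "bcr_pref_down")
  expect_equal(classify_gene(1 / 3, 1 / 2.9, 50), "shared_down")
  # no change: unchanged vs low_expressed on resting abundance
  expect_equal(classify_gene(1.5, 1.4, 50, min_expr = 1), "unchanged")
  expect_equal(classify_gene(1.5, 1.4, 0.5, min_expr = 1), "low_expressed")
})

test_that("noise-free planted tables are recovered exactly and labels partition", {
  cfg <- sim_config(
    seed = 42,
    n_genes = c(shared_up = 30, bcr_pref_up = 30, lps_pref_up = 30,
                shared_down = 30, bcr_pref_down = 30, unchanged = 30),
    expr_base_sdlog = 0, expr_dispersion = 0)
  ds <- generate_dataset(cfg, what = "expression")
  cls <- build_gene_sets(ds$expression)
  expect_equal(nrow(cls), 180)
  expect_true(all(table(cls$gene_id) == 1))           # partition
  expect_equal(unname(cls$label),
               unname(ds$truth$gene_class[cls$gene_id]))
})

test_that("an all-zero table is entirely low_expressed", {
  tab <- data.frame(gene_id = c("a", "b"), rest = 0, BCR120 = 0,
                    LPS120 = 0)
  expect_equal(build_gene_sets(tab)$label, c("low_expressed",
                                             "low_expressed"))
  expect_error(build_gene_sets(tab[, 1:3]), "lacks column")
})

test_that("swapping the stimulations swaps the preferential labels", {
  set.seed(7)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:300),
                    rest = rlnorm(300, log(30), 1),
                    BCR120 = rlnorm(300, log(30), 1.5),
                    LPS120 = rlnorm(300, log(30), 1.5))
  fwd <- build_gene_sets(tab)
  swp <- build_gene_sets(transform(tab, BCR120 = LPS120,
                                   LPS120 = BCR120))
  map <- c(shared_up = "shared_up", shared_down = "shared_down",
           unchanged = "unchanged", low_expressed = "low_expressed",
           bcr_pref_up = "lps_pref_up", lps_pref_up = "bcr_pref_up",
           bcr_pref_down = "lps_pref_down",
           lps_pref_down = "bcr_pref_down")
  expect_equal(unname(map[fwd$label]), swp$label)
})

test_that("raising the BCR fold never demotes a BCR-preferential gene", {
  for (fl in c(0.8, 1.5, 2.0, 2.9, 4.0, 5.0)) {
    labels <- vapply(seq(2, 12, by = 0.25), function(fb)
      classify_gene(fb, fl, 50), character(1))
    hit <- which(labels == "bcr_pref_up")
    if (length(hit))
      expect_true(all(labels[seq(min(hit), length(labels))] ==
                        "bcr_pref_up"),
                  info = sprintf("fold_lps = %g", fl))
  }
})
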