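test_that("pwm objects validate their matrix", {
  m <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_s3_class(pwm("M1", m), "pwm")
  expect_error(pwm("M1", m[1:3, ]), "4 rows")
  expect_error(pwm("M1", m[, 1:3]), "length")
  bad <- m; bad[1, 1] <- 0.5
  expect_error(pwm("M1", bad), "sum to 1")
})

test_that("the JASPAR-style library round-trips through text", {
  set.seed(3)
  pwms <- list(consensus_pwm("MA001", "ACGTACGT"),
               consensus_pwm("MB002", "TTTTGGGGCC"))
  names(pwms) <- c("MA001", "MB002")
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_pwms(pwms, f)
  back <- read_pwms(f)
  expect_equal(names(back), names(pwms))
  expect_equal(back$MA001$mat, pwms$MA001$mat, tolerance = 1e-6)
  expect_equal(back$MB002$mat, pwms$MB002$mat, tolerance = 1e-6)
})

test_that("promoter extraction honours coordinates and strand", {
  set.seed(4)
  chr <- random_dna(12000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  ann <- make_annotation(tss = c(5000, 9000), strand = c("+", "-"))
  prom <- extract_promoters(ann, genome)
  expect_equal(unname(as.character(prom[["g01"]])),
               substr(chr, 4001, 6001))        # [4000, 6001) 0-based
  expect_equal(unname(as.character(prom[["g02"]])),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 8001, 10001)))))
  single <- extract_promoters(ann, genome, window = c(0, 0))
  expect_equal(nchar(as.character(single[["g01"]])), 1)
  expect_equal(unname(as.character(single[["g01"]])),
               substr(chr, 5001, 5001))
  # TSS too close to the edge is skipped with a warning
  edge <- make_annotation(tss = 500, strand = "+")
  expect_warning(none <- extract_promoters(edge, genome), "skipped")
  expect_equal(length(none), 0)
})

test_that("the scan finds planted consensus occurrences on both strands", {
  set.seed(14)
  p <- consensus_pwm("M1", "ACGTTGCAAC")
  seq <- paste0(strrep("A", 40), "ACGTTGCAAC", strrep("C", 50))
  hits <- scan_promoter(seq, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 41)
  expect_equal(hits$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  rhits <- scan_promoter(rc, p)
  expect_equal(nrow(rhits), 1)
  expect_equal(rhits$strand, "-")
  # mirrored start: S - (offset + L - 1) + 1
  expect_equal(rhits$offset, nchar(seq) - (41 + 10 - 1) + 1)
  expect_equal(nrow(scan_promoter(strrep("N", 100), p)), 0)
  expect_equal(nrow(scan_promoter("ACGT", p)), 0)   # shorter than motif
})

test_that("enrichment p-values equal direct hypergeometric summation", {
  expect_equal(enrichment_test(8, 10, 10, 100), hyper_tail_p(8, 10, 10, 100))
  expect_equal(enrichment_test(10, 10, 100, 100), 1)
  expect_equal(enrichment_test(0, 10, 55, 100), 1)
  expect_error(enrichment_test(5, 0, 1, 10), "fg_total")
  expect_error(enrichment_test(11, 10, 1, 10), "inconsistent")
  # swapping an enriched foreground with its background moves p toward 1
  p_fwd <- enrichment_test(40, 100, 5, 100)
  p_swp <- enrichment_test(5, 100, 40, 100)
  expect_lt(p_fwd, 1e-6)
  expect_gt(p_swp, p_fwd)
})

test_that("hit counting is strand-symmetric and ZOOPS", {
  set.seed(15)
  p <- consensus_pwm("M1", "ACGTTGCAAC")
  seqs <- vapply(1:30, function(i) random_dna(400), character(1))
  # plant two occurrences in the first 10 sequences: still one hit each
  seqs[1:10] <- paste0("ACGTTGCAAC", substr(seqs[1:10], 11, 300),
                       "ACGTTGCAAC")
  fg <- Biostrings::DNAStringSet(seqs[1:15])
  bg <- Biostrings::DNAStringSet(seqs[16:30])
  res <- motif_enrichment(fg, bg, list(M1 = p))
  expect_equal(res$fg_hits, 10)
  res_rc <- motif_enrichment(Biostrings::reverseComplement(fg),
                             Biostrings::reverseComplement(bg),
                             list(M1 = p))
  expect_equal(res_rc$fg_hits, res$fg_hits)
  expect_equal(res_rc$bg_hits, res$bg_hits)
})

test_that("top-k lists behave at the identical and disjoint extremes", {
  mk <- function(ids, ps) data.frame(motif = ids, fg_hits = 5,
                                     fg_total = 10, bg_hits = 1,
                                     bg_total = 10, p_value = ps,
                                     neg_log10_p = -log10(ps))
  a <- mk(sprintf("M%02d", 1:10), seq(0.001, 0.1, length.out = 10))
  same <- top_k_overlap(list(x = a, y = a), k = 5)
  expect_equal(same$overlap["x", "y"], 5)
  b <- a; b$p_value <- rev(b$p_value); b$neg_log10_p <- -log10(b$p_value)
  disj <- top_k_overlap(list(x = a, y = b), k = 5)
  expect_equal(disj$overlap["x", "y"], 0)
  expect_error(top_k_overlap(list(x = a), k = 11), "fewer than")
})

test_that("a family-planted motif is recovered against the background", {
  cfg <- sim_config(seed = 17,
                    n_genes = c(bcr_pref_up = 60, unchanged = 60),
                    motif_plant_rate = 0.5, motif_background_rate = 0.05)
  ds <- generate_dataset(cfg, what = "sequence")
  prom <- extract_promoters(ds$annotation, ds$genome)
  sets <- split(ds$genes$gene_id, ds$genes$class)
  res <- motif_enrichment(prom[sets$bcr_pref_up], prom[sets$unchanged],
                          ds$pwms["M031"])   # BCR-only family member
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$fg_hits / res$fg_total, 0.3)
  expect_lt(res$bg_hits / res$bg_total, 0.2)
})
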