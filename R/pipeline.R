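#' Run the full analysis pipeline on a synthetic dataset
#'
#' Sequences every stage end to end: simulate, write the standard files,
#' classify genes from the expression table, build TSS metagene profiles
#' and region-score comparisons for Pol II and both histone marks, compute
#' traveling ratios, test promoter motif enrichment of the induced sets
#' against the unchanged-gene background with the top-k overlap
#' comparison, categorize miRNAs, and classify promoters by CpG proximity.
#' All randomness flows from `config$seed`; two runs with the same config
#' write byte-identical JSON summaries.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; per-module TSVs, profile matrices and
#'   a `summary.json` are written beneath it (`data/` holds the simulated
#'   standard files).
#' @param params Named list overriding analysis parameters:
#'   `pseudocount` (1), `threshold` (2), `min_expr` (1), `pref_band`
#'   (c(2, 4)), `profile_window` (c(-2000, 2000)), `h3k27_window`
#'   (c(-4000, 4000)), `score_window` (c(-1000, 1000)), `promoter_window`
#'   (c(-300, 300)), `body_window` (c(301, 2250)), `motif_window`
#'   (c(-1000, 1000)), `score_fraction` (0.8), `top_k` (30), `cpg_max_dist`
#'   (200), `anchor_mode` ("all_tss"), `min_set_size` (5),
#'   `write_data` (TRUE).
#' @return Invisibly, a list with every intermediate result and the
#'   summary written to `summary.json`.
#' @export
run_pipeline <- function(config, out_dir, params = list()) {
  p <- modifyList(list(
    pseudocount = 1, threshold = 2, min_expr = 1, pref_band = c(2, 4),
    profile_window = c(-2000L, 2000L), h3k27_window = c(-4000L, 4000L),
    score_window = c(-1000L, 1000L), promoter_window = c(-300L, 300L),
    body_window = c(301L, 2250L), motif_window = c(-1000L, 1000L),
    score_fraction = 0.8, top_k = 30L, cpg_max_dist = 200L,
    anchor_mode = "all_tss", min_set_size = 5L, write_data = TRUE),
    params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  dataset <- generate_dataset(config)
  if (isTRUE(p$write_data)) write_dataset(dataset, pth("data"))

  ## --- expression classification ---------------------------------------
  classification <- build_gene_sets(dataset$expression,
                                    pseudocount = p$pseudocount,
                                    threshold = p$threshold,
                                    min_expr = p$min_expr,
                                    pref_band = p$pref_band)
  .write_tsv(classification, pth("classification.tsv"))
  sets_all <- gene_sets(classification)
  set_sizes <- vapply(sets_all, length, integer(1))
  profile_sets <- intersect(c("shared_up", "bcr_pref_up", "lps_pref_up",
                              "unchanged"), names(sets_all))
  profile_sets <- profile_sets[set_sizes[profile_sets] >= p$min_set_size]

  polII <- dataset$tracks$polII
  ann <- dataset$annotation

  ## --- metagene profiles -----------------------------------------------
  profiles <- list()
  skipped_anchors <- 0L
  for (sig in names(dataset$tracks)) {
    win <- if (sig == "h3k27me3") p$h3k27_window else p$profile_window
    mat <- data.frame(offset = seq.int(win[1], win[2]))
    for (set in profile_sets) {
      for (cond in CONDITIONS) {
        prof <- withCallingHandlers(
          metagene_profile(dataset$tracks[[sig]][[cond]], ann,
                           sets_all[[set]], window = win,
                           anchor_mode = p$anchor_mode,
                           polII_track = polII[[cond]]),
          warning = function(w) invokeRestart("muffleWarning"))
        skipped_anchors <- skipped_anchors + prof$n_skipped
        mat[[paste(set, cond, sep = ".")]] <- prof$mean_rpm
      }
    }
    .write_tsv(mat, pth(sprintf("profiles_%s.tsv", sig)))
    profiles[[sig]] <- mat
  }

  ## --- region scores and rank-sum comparisons --------------------------
  score_tests <- list()
  for (sig in names(dataset$tracks)) {
    for (set in profile_sets) {
      sc <- lapply(CONDITIONS, function(cond)
        region_scores(dataset$tracks[[sig]][[cond]], ann,
                      sets_all[[set]], window = p$score_window,
                      anchor_mode = p$anchor_mode,
                      polII_track = polII[[cond]]))
      names(sc) <- CONDITIONS
      for (cmp in list(c("BCR", "rest"), c("LPS", "rest"),
                       c("BCR", "LPS"))) {
        rs <- rank_sum_test(sc[[cmp[1]]]$score, sc[[cmp[2]]]$score)
        score_tests[[length(score_tests) + 1L]] <- data.frame(
          signal = sig, gene_set = set, comparison = paste(cmp,
                                                           collapse = "_vs_"),
          statistic = rs$statistic, p_value = rs$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  score_tests <- do.call(rbind, score_tests)
  .write_tsv(score_tests, pth("region_score_tests.tsv"))

  ## --- traveling ratios -------------------------------------------------
  trs <- tr_table(polII, ann, sets_all[profile_sets],
                  promoter_window = p$promoter_window,
                  body_window = p$body_window,
                  anchor_mode = p$anchor_mode)
  .write_tsv(trs, pth("traveling_ratios.tsv"))

  ## --- motif enrichment --------------------------------------------------
  motifs <- NULL; overlap <- NULL
  up_sets <- intersect(c("shared_up", "bcr_pref_up", "lps_pref_up"),
                       profile_sets)
  if (!is.null(dataset$genome) && "unchanged" %in% names(sets_all) &&
      length(up_sets)) {
    promoters <- extract_promoters(ann, dataset$genome,
                                   window = p$motif_window)
    bg <- promoters[intersect(names(promoters), sets_all$unchanged)]
    enr <- lapply(up_sets, function(set) {
      fg <- promoters[intersect(names(promoters), sets_all[[set]])]
      motif_enrichment(fg, bg, dataset$pwms,
                       score_fraction = p$score_fraction)
    })
    names(enr) <- up_sets
    for (set in up_sets)
      .write_tsv(enr[[set]], pth(sprintf("motif_enrichment_%s.tsv", set)))
    motifs <- enr
    if (all(vapply(enr, nrow, integer(1)) >= p$top_k)) {
      overlap <- top_k_overlap(enr, k = p$top_k)
      .write_tsv(overlap$neg_log10_p, pth("motif_neg_log10_p.tsv"))
      .write_tsv(as.data.frame(overlap$overlap),
                 pth("motif_top_k_overlap.tsv"))
    }
  }

  ## --- miRNA categories --------------------------------------------------
  mirna <- categorize_mirna(dataset$mirna$normalized,
                            pseudocount = p$pseudocount,
                            threshold = p$threshold)
  .write_tsv(mirna, pth("mirna_categories.tsv"))
  mir_counts <- mirna_category_counts(mirna)

  ## --- CpG proximity -----------------------------------------------------
  cpg_calls <- classify_cpg(ann, dataset$cpg_islands,
                            max_dist = p$cpg_max_dist)
  .write_tsv(cpg_calls, pth("cpg_calls.tsv"))
  cpg_props <- withCallingHandlers(
    set_proportions(classification[, c("gene_id", "label")], cpg_calls),
    warning = function(w) invokeRestart("muffleWarning"))

  ## --- summary -----------------------------------------------------------
  summary <- list(
    parameters = c(list(seed = config$seed,
                        n_genes = as.list(config$n_genes)),
                   p[c("pseudocount", "threshold", "min_expr", "pref_band",
                       "profile_window", "h3k27_window", "score_window",
                       "promoter_window", "body_window", "motif_window",
                       "score_fraction", "top_k", "cpg_max_dist",
                       "anchor_mode")]),
    set_sizes = as.list(set_sizes),
    true_class_sizes = as.list(config$n_genes),
    skipped_anchors = skipped_anchors,
    traveling_ratio = trs,
    rank_sum_tests = score_tests,
    top_k_overlap = if (!is.null(overlap))
      as.data.frame(overlap$overlap) else NULL,
    mirna_counts = as.list(mir_counts$counts),
    mirna_changed = mir_counts$n_changed,
    cpg_proportions = cpg_props$proportions)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(dataset = dataset, classification = classification,
                 gene_sets = sets_all, profiles = profiles,
                 score_tests = score_tests, traveling_ratios = trs,
                 motifs = motifs, overlap = overlap, mirna = mirna,
                 mirna_counts = mir_counts, cpg_calls = cpg_calls,
                 cpg_proportions = cpg_props, summary = summary,
                 summary_path = pth("summary.json")))
}
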