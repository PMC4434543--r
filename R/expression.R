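#' Linear fold change with pseudocount
#'
#' `(stim + pseudocount) / (rest + pseudocount)`.  The pseudocount keeps
#' ratios finite for silent genes; with both abundances zero the fold is 1.
#'
#' @param rest,stim Non-negative normalized abundances (recycled).
#' @param pseudocount Positive abundance added to both terms (default 1).
#' @return Strictly positive fold change(s), linear scale.
#' @export
fold_change <- function(rest, stim, pseudocount = 1) {
  if (pseudocount <= 0) stop_config("pseudocount must be > 0")
  if (any(rest < 0) || any(stim < 0))
    stop_config("abundances must be non-negative")
  (stim + pseudocount) / (rest + pseudocount)
}

#' Twofold differential-expression call
#'
#' Boundary-inclusive: `up` iff `fold >= threshold`, `down` iff
#' `fold <= 1/threshold`, else `none` ("a minimal twofold difference" is
#' read as including the boundary).
#'
#' @param fold Positive linear fold change(s).
#' @param threshold Fold threshold > 1 (default 2).
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
call_de <- function(fold, threshold = 2) {
  if (threshold <= 1) stop_config("threshold must be > 1")
  if (any(fold <= 0)) stop_config("folds must be > 0")
  ifelse(fold >= threshold, "up",
         ifelse(fold <= 1 / threshold, "down", "none"))
}

# Vectorized classification core shared by classify_gene / build_gene_sets.
.classify_folds <- function(fold_bcr, fold_lps, rest_abundance, min_expr,
                            threshold = 2, pref_band = c(2, 4)) {
  de_b <- call_de(fold_bcr, threshold)
  de_l <- call_de(fold_lps, threshold)
  n <- length(fold_bcr)
  lab <- character(n)
  for (i in seq_len(n)) {
    fb <- fold_bcr[i]; fl <- fold_lps[i]
    if (de_b[i] == "up" || de_l[i] == "up") {
      if (de_b[i] == "up" && de_l[i] == "up") {
        lab[i] <-
          if (fl >= pref_band[1] && fl <= pref_band[2] && fb >= 2 * fl)
            "bcr_pref_up"
          else if (fb >= pref_band[1] && fb <= pref_band[2] && fl >= 2 * fb)
            "lps_pref_up"
          else "shared_up"
      } else {
        # induced by exactly one response (takes precedence over a
        # simultaneous decrease in the other response)
        lab[i] <- if (de_b[i] == "up") "bcr_pref_up" else "lps_pref_up"
      }
    } else if (de_b[i] == "down" || de_l[i] == "down") {
      rb <- 1 / fb; rl <- 1 / fl
      if (de_b[i] == "down" && de_l[i] == "down") {
        lab[i] <-
          if (rl >= pref_band[1] && rl <= pref_band[2] && rb >= 2 * rl)
            "bcr_pref_down"
          else if (rb >= pref_band[1] && rb <= pref_band[2] && rl >= 2 * rb)
            "lps_pref_down"
          else "shared_down"
      } else {
        lab[i] <- if (de_b[i] == "down") "bcr_pref_down" else "lps_pref_down"
      }
    } else {
      lab[i] <- if (rest_abundance[i] >= min_expr) "unchanged"
                else "low_expressed"
    }
  }
  lab
}

#' Classify one gene from its two fold changes
#'
#' Implements the shared/preferential rule on the induced side, and
#' symmetrically (on reciprocal folds) on the reduced side:
#' a gene changed by exactly one response is preferential to it; a gene
#' changed by both is preferential to one response when the other response's
#' fold lies within the two-to-fourfold band and the preferred fold is at
#' least twice the other, and shared otherwise; a gene changed by neither is
#' `unchanged` when its resting abundance reaches `min_expr`, else
#' `low_expressed`.
#'
#' @param fold_bcr,fold_lps Positive linear folds (stimulated/rest).
#' @param rest_abundance Resting-state abundance.
#' @param min_expr Minimum resting abundance for the `unchanged` set.
#' @param threshold Twofold DE threshold (default 2).
#' @param pref_band Inclusive fold band of the non-preferred response for
#'   the both-changed preferential call (default `c(2, 4)`).
#' @return One of `shared_up`, `shared_down`, `bcr_pref_up`,
#'   `bcr_pref_down`, `lps_pref_up`, `lps_pref_down`, `unchanged`,
#'   `low_expressed`.
#' @export
classify_gene <- function(fold_bcr, fold_lps, rest_abundance = Inf,
                          min_expr = 1, threshold = 2, pref_band = c(2, 4)) {
  .classify_folds(fold_bcr, fold_lps, rest_abundance, min_expr,
                  threshold, pref_band)
}

#' Classify every gene of an expression table
#'
#' Applies [classify_gene()] to the 120-min columns of a normalized
#' expression table (`rest`, `BCR120`, `LPS120` required; 30-min columns,
#' when present, are carried through for reporting only).
#'
#' @param table Data frame with a `gene_id` column and condition columns.
#' @param pseudocount,threshold,min_expr,pref_band See [fold_change()] and
#'   [classify_gene()].
#' @return The table's `gene_id` column plus `fold_bcr`, `fold_lps`,
#'   `de_bcr`, `de_lps`, `label`.  Labels partition the genes.
#' @export
build_gene_sets <- function(table, pseudocount = 1, threshold = 2,
                            min_expr = 1, pref_band = c(2, 4)) {
  need <- c("gene_id", "rest", "BCR120", "LPS120")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_config("expression table lacks column(s): %s",
                paste(miss, collapse = ", "))
  if (anyDuplicated(table$gene_id))
    stop_config("gene ids must be unique")
  fb <- fold_change(table$rest, table$BCR120, pseudocount)
  fl <- fold_change(table$rest, table$LPS120, pseudocount)
  data.frame(
    gene_id = table$gene_id,
    fold_bcr = fb, fold_lps = fl,
    de_bcr = call_de(fb, threshold), de_lps = call_de(fl, threshold),
    label = .classify_folds(fb, fl, table$rest, min_expr, threshold,
                            pref_band),
    stringsAsFactors = FALSE)
}

#' Split a classification into gene-id sets
#'
#' @param classification Output of [build_gene_sets()].
#' @return Named list `label -> character vector of gene ids`.
#' @export
gene_sets <- function(classification) {
  split(classification$gene_id, classification$label)
}
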