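#' Categorize miRNAs by the twofold rule
#'
#' Applies [fold_change()] and [call_de()] (the same primitives as the mRNA
#' classification, with the same pseudocount and boundary-inclusive
#' conventions) to a table of normalized miRNA reads, and maps the
#' per-condition direction pair to one of nine categories, including the
#' two opposing-direction sets.  No two-to-fourfold preferential rule is
#' applied to miRNAs — only the plain twofold rule.
#'
#' @param table Data frame with columns `mirna_id`, `rest`, `BCR`, `LPS`
#'   (normalized reads, non-negative, unique ids).
#' @param pseudocount,threshold See [fold_change()] and [call_de()].
#' @return Data frame: `mirna_id`, `fold_bcr`, `fold_lps`, `de_bcr`,
#'   `de_lps`, `category`.  Categories partition the miRNAs.
#' @export
categorize_mirna <- function(table, pseudocount = 1, threshold = 2) {
  need <- c("mirna_id", "rest", "BCR", "LPS")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_config("miRNA table lacks column(s): %s",
                paste(miss, collapse = ", "))
  if (anyDuplicated(table$mirna_id)) stop_config("miRNA ids must be unique")
  fb <- fold_change(table$rest, table$BCR, pseudocount)
  fl <- fold_change(table$rest, table$LPS, pseudocount)
  db <- call_de(fb, threshold)
  dl <- call_de(fl, threshold)
  key <- paste(db, dl, sep = "/")
  category <- c("up/up" = "up_both", "down/down" = "down_both",
                "up/none" = "up_bcr_only", "none/up" = "up_lps_only",
                "down/none" = "down_bcr_only",
                "none/down" = "down_lps_only",
                "up/down" = "up_bcr_down_lps",
                "down/up" = "down_bcr_up_lps",
                "none/none" = "unchanged")[key]
  data.frame(mirna_id = table$mirna_id, fold_bcr = fb, fold_lps = fl,
             de_bcr = db, de_lps = dl, category = unname(category),
             stringsAsFactors = FALSE)
}

#' Summary counts of miRNA categories
#'
#' @param categories Output of [categorize_mirna()].
#' @return List: `counts` (named category counts, all nine categories),
#'   `n_changed` (miRNAs in any non-`unchanged` category), and `opposing`
#'   (the two opposing-direction counts).
#' @export
mirna_category_counts <- function(categories) {
  levels <- c("up_both", "down_both", "up_bcr_only", "up_lps_only",
              "down_bcr_only", "down_lps_only", "up_bcr_down_lps",
              "down_bcr_up_lps", "unchanged")
  counts <- table(factor(categories$category, levels = levels))
  list(counts = stats::setNames(as.integer(counts), levels),
       n_changed = sum(categories$category != "unchanged"),
       opposing = c(up_bcr_down_lps = sum(categories$category ==
                                            "up_bcr_down_lps"),
                    down_bcr_up_lps = sum(categories$category ==
                                            "down_bcr_up_lps")))
}
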