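#' Generate a synthetic early-activation dataset
#'
#' Draws a complete seeded dataset with the statistical structure the
#' downstream analyses assume: gene annotation with 1-3 transcripts per
#' gene, nine coverage tracks (Pol II / H3K4me3 / H3K27me3 under rest / BCR
#' / LPS), a normalized expression table with planted per-class fold
#' changes, a promoter-bearing genome with planted motif occurrences and a
#' PWM library, a miRNA table with planted categories, CpG islands, and the
#' ground truth for all of it.
#'
#' The coverage model is per-base Poisson counts around the expected RPM
#' profile (a read simulator adds nothing for RPM-level profiling): Pol II
#' is a Gaussian promoter peak (at the dominant TSS) plus a uniform body
#' density over oriented offsets +301..gene end; H3K4me3 is two Gaussians at
#' the configured flank offsets (the upstream one at 70% height); H3K27me3
#' is a uniform domain centered on the TSS.  A uniform background density
#' covers the whole chromosome.
#'
#' Each component draws from its own sub-seed (`seed + 0..5` for
#' annotation, coverage, expression, sequence/motifs, miRNA, CpG), so a
#' fixed seed gives byte-identical output regardless of which other
#' components are requested.
#'
#' @param config A [sim_config()].
#' @param what Components to generate besides the annotation (always
#'   produced).  Any subset of `"coverage"`, `"expression"`, `"sequence"`,
#'   `"mirna"`, `"cpg"`.
#' @param signals Coverage signals to simulate, subset of
#'   `c("polII", "h3k4me3", "h3k27me3")`.
#' @return A `bstim_dataset` list: `config`, `genes` (one row per gene),
#'   `annotation` (one row per transcript), `tracks` (signal -> condition ->
#'   [coverage_track()]), `expression`, `genome` (DNAStringSet), `pwms`,
#'   `mirna` (list: `normalized`, `counts`, `library_sizes`), `cpg_islands`,
#'   and `truth`.
#' @export
generate_dataset <- function(config,
                             what = c("coverage", "expression", "sequence",
                                      "mirna", "cpg"),
                             signals = c("polII", "h3k4me3", "h3k27me3")) {
  config <- validate_sim_config(config)
  what <- match.arg(what, several.ok = TRUE)
  signals <- match.arg(signals, several.ok = TRUE)

  layout <- withr::with_seed(config$seed, .sim_genes(config))
  ds <- list(config = config, genes = layout$genes,
             annotation = layout$annotation)
  truth <- list(
    gene_class = stats::setNames(layout$genes$class, layout$genes$gene_id),
    class_sizes = config$n_genes,
    expected_tr = .expected_tr_table(config))

  if ("coverage" %in% what) {
    ds$tracks <- withr::with_seed(
      config$seed + 1L, .sim_tracks(config, layout$genes, signals))
  }
  if ("expression" %in% what) {
    ds$expression <- withr::with_seed(
      config$seed + 2L, .sim_expression(config, layout$genes))
  }
  if ("sequence" %in% what) {
    seqres <- withr::with_seed(
      config$seed + 3L, .sim_sequence(config, layout$genes))
    ds$genome <- seqres$genome
    ds$pwms <- seqres$pwms
    truth$motif_families <- config$motif_families
    truth$motif_plants <- seqres$plants
  }
  if ("mirna" %in% what) {
    mir <- withr::with_seed(config$seed + 4L, .sim_mirna(config))
    ds$mirna <- mir[c("normalized", "counts", "library_sizes")]
    truth$mirna_category <- mir$category
  }
  if ("cpg" %in% what) {
    cpg <- withr::with_seed(config$seed + 5L, .sim_cpg(config, layout$genes))
    ds$cpg_islands <- cpg$islands
    truth$cpg <- cpg$truth
  }
  ds$truth <- truth
  class(ds) <- "bstim_dataset"
  ds
}

#' @export
print.bstim_dataset <- function(x, ...) {
  cat("bstim_dataset:", nrow(x$genes), "genes /", nrow(x$annotation),
      "transcripts on", x$config$chrom, "\n")
  cat("  components:",
      paste(intersect(c("tracks", "expression", "genome", "mirna",
                        "cpg_islands"), names(x)), collapse = ", "), "\n")
  invisible(x)
}

# ---- gene layout ----------------------------------------------------------

.sim_genes <- function(cfg) {
  classes <- rep(names(cfg$n_genes), times = cfg$n_genes)
  n <- length(classes)
  if (n == 0L) {
    genes <- data.frame(gene_id = character(), class = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        tss = integer(), stringsAsFactors = FALSE)
    ann <- cbind(genes[0, ], tx_id = character(), tx_rank = integer())
    return(list(genes = genes, annotation = ann[, c(
      "gene_id", "tx_id", "tx_rank", "class", "chrom", "start", "end",
      "strand", "tss")]))
  }
  pitch <- cfg$gene_length + cfg$flank
  start <- cfg$flank + (seq_len(n) - 1L) * pitch
  end <- start + cfg$gene_length
  # alternate strands within each class so both orientations are exercised
  strand <- unlist(lapply(cfg$n_genes, function(k)
    rep_len(c("+", "-"), k)), use.names = FALSE)
  tss <- ifelse(strand == "+", start, end - 1L)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)), class = classes,
    chrom = cfg$chrom, start = start, end = end, strand = strand,
    tss = as.integer(tss), stringsAsFactors = FALSE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (cfg$n_tss_range[2] > cfg$n_tss_range[1])
      sample(seq.int(cfg$n_tss_range[1], cfg$n_tss_range[2]), 1L)
    else cfg$n_tss_range[1]
    jit <- integer(k)
    if (k > 1L) {
      jr <- cfg$tss_jitter_range
      mag <- if (jr[2] > jr[1]) sample(seq.int(jr[1], jr[2]), k - 1L,
                                       replace = TRUE)
             else rep(jr[1], k - 1L)
      jit[-1L] <- mag * sample(c(-1L, 1L), k - 1L, replace = TRUE)
    }
    tss_k <- genes$tss[i] + jit
    # transcript extent encodes its own TSS: it runs from the (possibly
    # jittered) TSS to the shared gene end
    if (genes$strand[i] == "+") {
      tx_start <- tss_k; tx_end <- rep(genes$end[i], k)
    } else {
      tx_start <- rep(genes$start[i], k); tx_end <- tss_k + 1L
    }
    rows[[i]] <- data.frame(
      gene_id = genes$gene_id[i],
      tx_id = sprintf("%s.t%d", genes$gene_id[i], seq_len(k)),
      tx_rank = seq_len(k), class = genes$class[i], chrom = cfg$chrom,
      start = as.integer(tx_start), end = as.integer(tx_end),
      strand = genes$strand[i],
      tss = as.integer(tss_k), stringsAsFactors = FALSE)
  }
  list(genes = genes, annotation = do.call(rbind, rows))
}

# ---- coverage -------------------------------------------------------------

# Expected RPM-per-bp profile of one signal under one condition.
.expected_rpm <- function(cfg, genes, signal, condition) {
  L <- cfg$chrom_length
  v <- rep(cfg$background_rpm, L)
  add_gauss <- function(center, height, sd) {
    span <- ceiling(4 * sd)
    pos <- max(0L, center - span):min(L - 1L, center + span)
    v[pos + 1L] <<- v[pos + 1L] + height * exp(-((pos - center)^2) /
                                                 (2 * sd^2))
  }
  add_flat <- function(a, b, height) {   # 0-based inclusive bounds
    a <- max(0L, a); b <- min(L - 1L, b)
    if (b >= a) v[(a:b) + 1L] <<- v[(a:b) + 1L] + height
  }
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]; cl <- genes$class[i]
    sgn <- if (genes$strand[i] == "+") 1L else -1L
    if (signal == "polII") {
      pm <- .effect_mult(cfg$polII_effects, cl, "promoter", condition)
      bm <- .effect_mult(cfg$polII_effects, cl, "body", condition)
      add_gauss(tss, cfg$promoter_peak_height * pm, cfg$promoter_peak_sd)
      body <- sort(c(tss + sgn * 301L, tss + sgn * (cfg$gene_length - 1L)))
      add_flat(body[1], body[2], cfg$body_density * bm)
    } else if (signal == "h3k4me3") {
      m <- .effect_mult(cfg$h3k4_effects, cl, NULL, condition)
      h <- cfg$h3k4_peak_height * m
      add_gauss(tss + sgn * cfg$h3k4_peak_offsets[1], 0.7 * h,
                cfg$h3k4_peak_sd)
      add_gauss(tss + sgn * cfg$h3k4_peak_offsets[2], h, cfg$h3k4_peak_sd)
    } else if (signal == "h3k27me3") {
      m <- .effect_mult(cfg$h3k27_effects, cl, NULL, condition)
      add_flat(tss - cfg$h3k27_domain_halfwidth,
               tss + cfg$h3k27_domain_halfwidth, cfg$h3k27_height * m)
    }
  }
  v
}

.sim_tracks <- function(cfg, genes, signals) {
  tracks <- list()
  for (sig in signals) {
    tracks[[sig]] <- list()
    for (cond in CONDITIONS) {
      lib <- cfg$library_sizes[[sig]][[cond]]
      if (is.null(lib)) stop_config("no library size for %s/%s", sig, cond)
      lam <- .expected_rpm(cfg, genes, sig, cond) * lib / 1e6
      counts <- S4Vectors::Rle(rpois(length(lam), lam))
      tracks[[sig]][[cond]] <-
        coverage_track(stats::setNames(list(counts), cfg$chrom), lib)
    }
  }
  tracks
}

# Analytic traveling ratio implied by the coverage model, per class and
# condition (promoter -300..+300, body +301..+2250).
.expected_tr_table <- function(cfg) {
  G <- sum(exp(-((-300:300)^2) / (2 * cfg$promoter_peak_sd^2)))
  rows <- list()
  for (cl in names(cfg$n_genes)) {
    for (cond in CONDITIONS) {
      pm <- .effect_mult(cfg$polII_effects, cl, "promoter", cond)
      bm <- .effect_mult(cfg$polII_effects, cl, "body", cond)
      p <- cfg$promoter_peak_height * pm * G + cfg$background_rpm * 601
      b <- (cfg$body_density * bm + cfg$background_rpm) * 1950
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, condition = cond, tr = b / p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(class = character(), condition = character(),
                      tr = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---- expression -----------------------------------------------------------

.class_folds <- function(fold_map, class) {
  f <- fold_map[[class]]
  if (is.null(f)) c(BCR = 1, LPS = 1) else f
}

# class vector -> n x 2 fold matrix, safe for zero-length input
.fold_matrix <- function(fold_map, classes) {
  m <- matrix(numeric(0), ncol = 2,
              dimnames = list(NULL, c("BCR", "LPS")))
  if (length(classes))
    m <- t(vapply(classes, function(cl) .class_folds(fold_map, cl),
                  numeric(2)))
  colnames(m) <- c("BCR", "LPS")
  m
}

.nb_or_mean <- function(mu, dispersion) {
  if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else mu
}

.sim_expression <- function(cfg, genes) {
  n <- nrow(genes)
  base <- rlnorm(n, cfg$expr_base_meanlog, cfg$expr_base_sdlog)
  folds <- .fold_matrix(cfg$fold_map, genes$class)
  a <- cfg$t30_exponent
  data.frame(
    gene_id = genes$gene_id,
    rest   = .nb_or_mean(base, cfg$expr_dispersion),
    BCR30  = .nb_or_mean(base * folds[, "BCR"]^a, cfg$expr_dispersion),
    BCR120 = .nb_or_mean(base * folds[, "BCR"], cfg$expr_dispersion),
    LPS30  = .nb_or_mean(base * folds[, "LPS"]^a, cfg$expr_dispersion),
    LPS120 = .nb_or_mean(base * folds[, "LPS"], cfg$expr_dispersion),
    stringsAsFactors = FALSE)
}

# ---- promoter sequence and motifs -----------------------------------------

.random_pwm <- function(id, len) {
  consensus <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mat <- matrix(0.01, nrow = 4, ncol = len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(len)) mat[consensus[j], j] <- 0.97
  pwm(id, mat)
}

.sim_sequence <- function(cfg, genes, promoter_window = c(-1000L, 1000L)) {
  L <- cfg$chrom_length
  genome <- Biostrings::DNAString(paste(
    c("A", "C", "G", "T")[sample.int(4L, L, replace = TRUE)],
    collapse = ""))
  pwms <- lapply(names(cfg$motif_families), function(id)
    .random_pwm(id, cfg$motif_length))
  names(pwms) <- names(cfg$motif_families)

  width <- promoter_window[2] - promoter_window[1] + 1L
  starts <- integer(); ends <- integer(); segs <- character()
  plants <- list()
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]; st <- genes$strand[i]; cl <- genes$class[i]
    kept <- matrix(integer(), ncol = 2)   # occupied oriented intervals
    for (id in names(pwms)) {
      rate <- if (cl %in% cfg$motif_families[[id]]) cfg$motif_plant_rate
              else cfg$motif_background_rate
      if (runif(1) >= rate) next
      Lm <- ncol(pwms[[id]]$mat)
      j <- sample.int(width - Lm + 1L, 1L)
      mstrand <- sample(c("+", "-"), 1L)
      if (nrow(kept) &&
          any(j <= kept[, 2] & (j + Lm - 1L) >= kept[, 1])) next
      kept <- rbind(kept, c(j, j + Lm - 1L))
      cons <- .pwm_consensus(pwms[[id]])
      if (st == "+") {
        gstart <- tss - 1000L + j              # 1-based
        seg <- if (mstrand == "+") cons else .revcomp(cons)
      } else {
        ghi <- tss + 1002L - j
        gstart <- ghi - Lm + 1L
        seg <- if (mstrand == "+") .revcomp(cons) else cons
      }
      starts <- c(starts, gstart); ends <- c(ends, gstart + Lm - 1L)
      segs <- c(segs, seg)
      plants[[length(plants) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], motif_id = id, offset = j,
        strand = mstrand, stringsAsFactors = FALSE)
    }
  }
  if (length(starts)) {
    genome <- Biostrings::replaceAt(
      genome, IRanges::IRanges(starts, ends),
      Biostrings::DNAStringSet(segs))
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(list(genome),
                                                     cfg$chrom))
  plants <- if (length(plants)) do.call(rbind, plants)
            else data.frame(gene_id = character(), motif_id = character(),
                            offset = integer(), strand = character(),
                            stringsAsFactors = FALSE)
  list(genome = genome, pwms = pwms, plants = plants)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.pwm_consensus <- function(p) {
  paste(rownames(p$mat)[apply(p$mat, 2, which.max)], collapse = "")
}

# ---- miRNA ----------------------------------------------------------------

.sim_mirna <- function(cfg) {
  cats <- rep(names(cfg$mirna_n), times = cfg$mirna_n)
  n <- length(cats)
  ids <- sprintf("mir-sim-%03d", seq_len(n))
  base <- rlnorm(n, cfg$mirna_base_meanlog, cfg$mirna_base_sdlog)
  folds <- .fold_matrix(cfg$mirna_fold_map, cats)
  libs <- cfg$mirna_library_sizes
  norm <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  counts <- data.frame(mirna_id = ids, stringsAsFactors = FALSE)
  mu_norm <- cbind(rest = base, BCR = base * folds[, "BCR"],
                   LPS = base * folds[, "LPS"])
  for (cond in CONDITIONS) {
    raw <- .nb_or_mean(mu_norm[, cond] * libs[[cond]] / 1e6,
                       cfg$mirna_dispersion)
    counts[[cond]] <- raw
    norm[[cond]] <- raw * 1e6 / libs[[cond]]
  }
  list(normalized = norm, counts = counts, library_sizes = libs,
       category = stats::setNames(cats, ids))
}

# ---- CpG islands ----------------------------------------------------------

.sim_cpg <- function(cfg, genes, max_gap = 200L) {
  rate_for <- function(cl) {
    r <- cfg$cpg_rate
    if (is.null(names(r))) r[1] else (r[[cl]] %||% 0)
  }
  isl <- list(); truth <- list()
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    assoc <- runif(1) < rate_for(genes$class[i])
    dist <- Inf
    if (assoc) {
      w <- sample(seq.int(cfg$cpg_width_range[1], cfg$cpg_width_range[2]),
                  1L)
      if (runif(1) < 0.7) {          # island contains the TSS
        s <- tss - (sample.int(w, 1L) - 1L)
        dist <- 0L
      } else {                       # island near the TSS, gap <= max_gap
        g <- sample.int(max_gap, 1L)
        s <- if (runif(1) < 0.5) tss - g - w else tss + g + 1L
        dist <- g
      }
      s <- max(0L, s); e <- min(cfg$chrom_length, s + w)
      isl[[length(isl) + 1L]] <- data.frame(
        chrom = cfg$chrom, start = s, end = e, stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], cpg_associated = assoc,
      distance = dist, stringsAsFactors = FALSE)
  }
  islands <- if (length(isl)) do.call(rbind, isl)
             else data.frame(chrom = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  rownames(islands) <- NULL
  list(islands = islands,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(),
                               cpg_associated = logical(),
                               distance = numeric(),
                               stringsAsFactors = FALSE))
}
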