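#' Configure a synthetic early-activation dataset
#'
#' Builds the parameter object consumed by [generate_dataset()].  Defaults
#' emulate, at desk scale, the structure of a three-condition (resting, BCR,
#' LPS) early B cell activation experiment: a large shared induced program
#' with small ligand-preferential subsets, ChIP-seq-like per-base coverage of
#' RNA polymerase II (promoter peak plus gene-body density), bimodal H3K4me3
#' and broad H3K27me3 promoter domains, negative-binomial expression with
#' planted per-class fold changes, promoter sequences with planted motif
#' families, twofold-categorized miRNA counts, and CpG islands at promoters.
#'
#' Coordinates are 0-based internally; genes are laid on one chromosome with
#' `flank` bp on each side (at least 5 kb is required so every profiling
#' window fits).  Condition-specific signal strengths are expressed as
#' multipliers of the resting-state parameters, per gene class (see
#' [default_polII_effects()]).
#'
#' @param seed Integer seed; every downstream draw derives from it.  Each
#'   dataset component uses `seed + k` (k = 0..5) so that generating a subset
#'   of components is reproducible.
#' @param n_genes Named integer vector, genes per class.  Class names are
#'   free-form, but the defaults use the classification labels so that the
#'   planted structure matches what [build_gene_sets()] recovers.
#' @param gene_length,flank Gene body length and inter/flanking spacing, bp.
#' @param chrom,chrom_length Chromosome name and length; length is computed
#'   from the gene layout when `NULL`, and validated otherwise.
#' @param n_tss_range Integer pair: each gene receives this many transcripts
#'   (sampled uniformly); the first transcript carries the dominant promoter
#'   peak.
#' @param tss_jitter_range Absolute jitter (bp) of secondary transcript TSSs,
#'   sampled uniformly from `[min, max]` with random sign.
#' @param background_rpm Uniform background coverage, RPM per bp, all tracks.
#' @param library_sizes Nested list `signal -> condition -> total mapped
#'   reads` used both to scale Poisson sampling and as the RPM denominator.
#' @param promoter_peak_height Pol II promoter peak height at the TSS, RPM/bp.
#' @param promoter_peak_sd Gaussian SD of the promoter peak, bp.
#' @param body_density Pol II gene-body density, RPM per bp, resting state.
#'   The body spans oriented offsets +301..gene end so that the promoter
#'   (-300..+300) and body (+301..+2250) windows partition cleanly.
#' @param polII_effects,h3k4_effects,h3k27_effects Per-class condition
#'   multipliers; see [default_polII_effects()] and friends.  Classes absent
#'   from the list default to 1 (no condition effect).
#' @param h3k4_peak_offsets Oriented offsets (bp) of the two H3K4me3 flank
#'   peaks relative to the TSS; the upstream peak is drawn at 70% height.
#' @param h3k4_peak_sd,h3k4_peak_height H3K4me3 peak shape parameters.
#' @param h3k27_domain_halfwidth,h3k27_height H3K27me3 uniform domain
#'   half-width (bp) and height (RPM/bp).
#' @param expr_base_meanlog,expr_base_sdlog Log-normal baseline abundance of
#'   genes (FPKM-like units).  `expr_base_sdlog = 0` fixes all baselines.
#' @param expr_dispersion Negative-binomial dispersion of expression values;
#'   `0` yields noise-free tables equal to their expectations.
#' @param t30_exponent The 30-min columns use `fold^t30_exponent` (partial
#'   response at the earlier time point).
#' @param fold_map Named list `class -> c(BCR = fold, LPS = fold)` applied at
#'   120 min; classes absent default to `c(1, 1)`.
#' @param mirna_n Named integer vector, miRNAs per category (category names
#'   as in [categorize_mirna()]).  Defaults reproduce, at face value, a study
#'   with 60 changed miRNAs of which 20 are LPS-increased and 29
#'   BCR-decreased.
#' @param mirna_fold_map Named list `category -> c(BCR, LPS)` fold vs. rest.
#' @param mirna_dispersion,mirna_base_meanlog,mirna_base_sdlog miRNA count
#'   model parameters (as for expression).
#' @param mirna_library_sizes Named vector of miRNA library sizes (reads).
#' @param motif_length Planted motif (consensus) length, bp.
#' @param motif_families Named list `motif id -> character vector of classes`
#'   in which the motif is planted at `motif_plant_rate`; motifs mapped to
#'   `character(0)` are decoys.  Defaults via [default_motif_families()].
#' @param motif_plant_rate,motif_background_rate Per-promoter probability of
#'   planting one consensus occurrence in target classes / everywhere else.
#' @param cpg_rate Named per-class probability that a promoter is
#'   CpG-associated (TSS within 200 bp of an island); a single unnamed value
#'   applies to all classes.
#' @param cpg_width_range CpG island width range, bp.
#'
#' @return A validated `sim_config` object (a list).
#' @seealso [generate_dataset()], [write_dataset()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = c(shared_up = 180L, bcr_pref_up = 10L,
                                   lps_pref_up = 10L, shared_down = 30L,
                                   bcr_pref_down = 20L, lps_pref_down = 2L,
                                   unchanged = 130L),
                       gene_length = 6000L,
                       flank = 6000L,
                       chrom = "chr1",
                       chrom_length = NULL,
                       n_tss_range = c(1L, 3L),
                       tss_jitter_range = c(100L, 200L),
                       background_rpm = 0.02,
                       library_sizes = list(
                         polII    = c(rest = 18.1e6, BCR = 14.2e6, LPS = 21.3e6),
                         h3k4me3  = c(rest = 13.1e6, BCR = 16.4e6, LPS = 19.1e6),
                         h3k27me3 = c(rest = 19.0e6, BCR = 20.0e6, LPS = 18.1e6)),
                       promoter_peak_height = 4,
                       promoter_peak_sd = 150,
                       body_density = 0.5,
                       polII_effects = default_polII_effects(),
                       h3k4_peak_offsets = c(-300L, 500L),
                       h3k4_peak_sd = 200,
                       h3k4_peak_height = 3,
                       h3k4_effects = default_h3k4_effects(),
                       h3k27_domain_halfwidth = 3000L,
                       h3k27_height = 0.8,
                       h3k27_effects = default_h3k27_effects(),
                       expr_base_meanlog = log(30),
                       expr_base_sdlog = 1,
                       expr_dispersion = 0.01,
                       t30_exponent = 0.5,
                       fold_map = default_fold_map(),
                       mirna_n = c(up_both = 4L, down_both = 4L,
                                   up_bcr_only = 2L, up_lps_only = 16L,
                                   down_bcr_only = 25L, down_lps_only = 2L,
                                   up_bcr_down_lps = 2L, down_bcr_up_lps = 5L,
                                   unchanged = 60L),
                       mirna_fold_map = default_mirna_fold_map(),
                       mirna_dispersion = 0.01,
                       mirna_base_meanlog = log(200),
                       mirna_base_sdlog = 1,
                       mirna_library_sizes = c(rest = 20.2e6, BCR = 28.6e6,
                                               LPS = 14.8e6),
                       motif_length = 10L,
                       motif_families = default_motif_families(names(n_genes)),
                       motif_plant_rate = 0.5,
                       motif_background_rate = 0.05,
                       cpg_rate = 0.75,
                       cpg_width_range = c(600L, 1500L)) {
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes,
    gene_length = as.integer(gene_length), flank = as.integer(flank),
    chrom = chrom, chrom_length = chrom_length,
    n_tss_range = as.integer(n_tss_range),
    tss_jitter_range = as.integer(tss_jitter_range),
    background_rpm = background_rpm, library_sizes = library_sizes,
    promoter_peak_height = promoter_peak_height,
    promoter_peak_sd = promoter_peak_sd, body_density = body_density,
    polII_effects = polII_effects,
    h3k4_peak_offsets = as.integer(h3k4_peak_offsets),
    h3k4_peak_sd = h3k4_peak_sd, h3k4_peak_height = h3k4_peak_height,
    h3k4_effects = h3k4_effects,
    h3k27_domain_halfwidth = as.integer(h3k27_domain_halfwidth),
    h3k27_height = h3k27_height, h3k27_effects = h3k27_effects,
    expr_base_meanlog = expr_base_meanlog,
    expr_base_sdlog = expr_base_sdlog,
    expr_dispersion = expr_dispersion, t30_exponent = t30_exponent,
    fold_map = fold_map,
    mirna_n = mirna_n, mirna_fold_map = mirna_fold_map,
    mirna_dispersion = mirna_dispersion,
    mirna_base_meanlog = mirna_base_meanlog,
    mirna_base_sdlog = mirna_base_sdlog,
    mirna_library_sizes = mirna_library_sizes,
    motif_length = as.integer(motif_length),
    motif_families = motif_families,
    motif_plant_rate = motif_plant_rate,
    motif_background_rate = motif_background_rate,
    cpg_rate = cpg_rate, cpg_width_range = as.integer(cpg_width_range))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", sum(x$n_genes), " genes in ", length(x$n_genes),
      " classes; seed ", x$seed, "\n", sep = "")
  cat("  classes:", paste0(names(x$n_genes), "(", x$n_genes, ")",
                           collapse = " "), "\n")
  cat("  chrom ", x$chrom, ", length ", .required_chrom_length(x), " bp\n",
      sep = "")
  cat("  motifs: ", length(x$motif_families), " (plant rate ",
      x$motif_plant_rate, ", background ", x$motif_background_rate, ")\n",
      sep = "")
  invisible(x)
}

.required_chrom_length <- function(cfg) {
  n <- sum(cfg$n_genes)
  cfg$flank * (n + 1L) + n * cfg$gene_length
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed) || cfg$seed < 0 || cfg$seed > 2^31 - 10)
    stop_config("seed must be a non-negative integer below 2^31 - 10")
  if (length(cfg$n_genes) && is.null(names(cfg$n_genes)))
    stop_config("n_genes must be a named vector (class -> count)")
  if (any(cfg$n_genes < 0)) stop_config("gene counts must be >= 0")
  if (cfg$flank < 5000L)
    stop_config("flank must be >= 5000 bp so profiling windows fit")
  if (cfg$gene_length < 2500L)
    stop_config("gene_length must be >= 2500 bp (body window reaches +2250)")
  need <- .required_chrom_length(cfg)
  if (is.null(cfg$chrom_length)) {
    cfg$chrom_length <- need
  } else if (cfg$chrom_length < need) {
    stop_config("chrom_length %d too small for %d genes (need >= %d)",
                cfg$chrom_length, sum(cfg$n_genes), need)
  }
  for (fm in c(cfg$fold_map, cfg$mirna_fold_map))
    if (any(fm <= 0)) stop_config("all fold values must be > 0")
  if (any(cfg$mirna_n < 0)) stop_config("miRNA counts must be >= 0")
  if (cfg$background_rpm < 0 || cfg$promoter_peak_height < 0 ||
      cfg$body_density < 0)
    stop_config("coverage densities must be >= 0")
  if (cfg$expr_dispersion < 0 || cfg$mirna_dispersion < 0)
    stop_config("dispersions must be >= 0")
  jr <- cfg$tss_jitter_range
  if (length(jr) != 2L || jr[1] < 0 || jr[2] > 200L || jr[1] > jr[2])
    stop_config("tss_jitter_range must lie within [0, 200] bp")
  if (cfg$n_tss_range[1] < 1L || cfg$n_tss_range[2] < cfg$n_tss_range[1])
    stop_config("n_tss_range must be an increasing pair with min >= 1")
  rates <- c(cfg$motif_plant_rate, cfg$motif_background_rate)
  if (any(rates < 0 | rates > 1)) stop_config("motif rates must be in [0, 1]")
  cfg
}

#' Default condition multipliers for the synthetic coverage model
#'
#' Per-class multipliers of resting-state parameters that encode the study's
#' qualitative signatures: BCR stimulation recruits additional Pol II to
#' promoters (globally, and most at BCR-preferential genes) with little gain
#' in body occupancy, while LPS stimulation increases body occupancy
#' (initiation-to-elongation transition); H3K4me3 rises under both stimuli
#' but more under LPS; H3K27me3 falls around the TSS under BCR and is largely
#' unchanged under LPS.
#'
#' @return Named list `class -> list(promoter = , body = )` (Pol II) or
#'   `class -> named condition vector` (histone marks).
#' @export
default_polII_effects <- function() {
  list(
    shared_up     = list(promoter = c(rest = 1, BCR = 2.0, LPS = 1.1),
                         body     = c(rest = 1, BCR = 1.2, LPS = 2.0)),
    bcr_pref_up   = list(promoter = c(rest = 1, BCR = 2.5, LPS = 1.0),
                         body     = c(rest = 1, BCR = 1.3, LPS = 1.0)),
    lps_pref_up   = list(promoter = c(rest = 1, BCR = 1.2, LPS = 1.2),
                         body     = c(rest = 1, BCR = 1.0, LPS = 2.5)),
    unchanged     = list(promoter = c(rest = 1, BCR = 1.5, LPS = 1.0),
                         body     = c(rest = 1, BCR = 1.0, LPS = 1.2)),
    shared_down   = list(promoter = c(rest = 1, BCR = 0.8, LPS = 0.9),
                         body     = c(rest = 1, BCR = 0.7, LPS = 0.7)),
    bcr_pref_down = list(promoter = c(rest = 1, BCR = 0.7, LPS = 1.0),
                         body     = c(rest = 1, BCR = 0.6, LPS = 1.0)),
    lps_pref_down = list(promoter = c(rest = 1, BCR = 1.0, LPS = 0.7),
                         body     = c(rest = 1, BCR = 1.0, LPS = 0.6)))
}

#' @rdname default_polII_effects
#' @export
default_h3k4_effects <- function() {
  list(
    shared_up     = c(rest = 1, BCR = 1.3, LPS = 1.8),
    bcr_pref_up   = c(rest = 1, BCR = 1.6, LPS = 1.8),
    lps_pref_up   = c(rest = 1, BCR = 1.3, LPS = 2.5),
    unchanged     = c(rest = 1, BCR = 1.3, LPS = 1.8),
    shared_down   = c(rest = 1, BCR = 0.9, LPS = 1.0),
    bcr_pref_down = c(rest = 1, BCR = 0.9, LPS = 1.0),
    lps_pref_down = c(rest = 1, BCR = 1.0, LPS = 0.9))
}

#' @rdname default_polII_effects
#' @export
default_h3k27_effects <- function() {
  list(
    shared_up     = c(rest = 1, BCR = 0.6, LPS = 0.95),
    bcr_pref_up   = c(rest = 1, BCR = 0.5, LPS = 1.0),
    lps_pref_up   = c(rest = 1, BCR = 0.7, LPS = 0.95),
    unchanged     = c(rest = 1, BCR = 0.7, LPS = 1.0),
    shared_down   = c(rest = 1, BCR = 1.0, LPS = 1.0),
    bcr_pref_down = c(rest = 1, BCR = 1.0, LPS = 1.0),
    lps_pref_down = c(rest = 1, BCR = 1.0, LPS = 1.0))
}

#' Default planted fold changes per gene class
#'
#' Linear-scale stimulated/resting fold at 120 min for each condition.
#' Values sit clear of the twofold and two-to-fourfold rule boundaries so
#' that noise-free tables are recovered exactly by [build_gene_sets()].
#' @return Named list `class -> c(BCR = fold, LPS = fold)`.
#' @export
default_fold_map <- function() {
  list(
    shared_up     = c(BCR = 4,     LPS = 4),
    bcr_pref_up   = c(BCR = 8,     LPS = 1),
    lps_pref_up   = c(BCR = 1,     LPS = 8),
    shared_down   = c(BCR = 0.25,  LPS = 0.25),
    bcr_pref_down = c(BCR = 0.125, LPS = 1),
    lps_pref_down = c(BCR = 1,     LPS = 0.125),
    unchanged     = c(BCR = 1,     LPS = 1))
}

#' @rdname default_fold_map
#' @export
default_mirna_fold_map <- function() {
  list(
    up_both         = c(BCR = 4,    LPS = 4),
    down_both       = c(BCR = 0.25, LPS = 0.25),
    up_bcr_only     = c(BCR = 4,    LPS = 1),
    up_lps_only     = c(BCR = 1,    LPS = 4),
    down_bcr_only   = c(BCR = 0.25, LPS = 1),
    down_lps_only   = c(BCR = 1,    LPS = 0.25),
    up_bcr_down_lps = c(BCR = 4,    LPS = 0.25),
    down_bcr_up_lps = c(BCR = 0.25, LPS = 4),
    unchanged       = c(BCR = 1,    LPS = 1))
}

#' Default motif family layout
#'
#' Assigns planted motif families to the induced gene sets: 30 motifs for
#' the shared set, of which 18 are also planted in BCR-preferential
#' promoters; 12 further BCR-unique motifs; 30 LPS-unique motifs; and 8
#' never-planted decoys.  Family membership of the top-30 enrichment lists
#' then mirrors the mutually exclusive motif signatures of the two
#' responses (large shared/BCR overlap, none with LPS).  Families targeting
#' classes absent from `classes` are kept (their motifs simply behave as
#' background-rate motifs).
#'
#' @param classes Character vector of class names present in the dataset.
#' @return Named list `motif id -> character vector of target classes`.
#' @export
default_motif_families <- function(classes = character()) {
  fam <- list()
  for (i in 1:30) {
    targets <- "shared_up"
    if (i >= 13) targets <- c(targets, "bcr_pref_up")   # 18 shared motifs
    fam[[sprintf("M%03d", i)]] <- targets
  }
  for (i in 31:42) fam[[sprintf("M%03d", i)]] <- "bcr_pref_up"
  for (i in 43:72) fam[[sprintf("M%03d", i)]] <- "lps_pref_up"
  for (i in 73:80) fam[[sprintf("M%03d", i)]] <- character(0)
  lapply(fam, function(t) intersect(t, classes))
}
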