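---
title: "Methods: models, parameters and design choices in bstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in bstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bstim` characterizes how B cell activation programs diverge between BCR
(anti-IgM) and TLR4 (LPS) stimulation relative to the resting state, from
three kinds of input: a gene × condition normalized expression table,
per-base coverage tracks for RNA polymerase II and the histone marks
H3K4me3/H3K27me3, and promoter sequence plus a PWM library.  This vignette
is the package's own account of each procedure, the parameters that matter,
and the choices made where the design was genuinely open.

## Gene-set classification

Fold changes are linear ratios with a pseudocount,
$f = (x_\text{stim} + c)/(x_\text{rest} + c)$, computed at the 120-min
columns.  A minimal twofold criterion on a linear ratio and $|\log_2 f| \ge
1$ are the same rule; we work on the linear scale and make all thresholds
boundary-inclusive (a *minimal* twofold change reads naturally as
$\ge$).  The classification rule, applied on the induced side and, on
reciprocal folds, symmetrically on the reduced side:

1. changed by exactly one response → preferential to it;
2. changed by both, the non-preferred fold within $[2, 4]$ and the
   preferred fold at least twice the non-preferred → preferential;
3. changed by both otherwise → shared;
4. changed by neither, resting abundance $\ge$ `min_expr` → unchanged,
   else low-expressed.

Because the $\ge 2\times$ fold-ratio requirement is antisymmetric, at most
one preferential direction can fire, so labels partition the genes.

Open points resolved here: a gene induced by one ligand and reduced by the
other is labelled on the induced side (the rule never contemplates the
case; the data it was written for had almost no ligand-selective
decreases, so the induced reading costs nothing and keeps the partition).
The pseudocount defaults to 1 abundance unit and `min_expr` (the floor
defining actively transcribed but unchanged genes) to 1; both are
tunable design choices — zero handling and the unchanged-set cutoff are
exactly the points such procedures leave unstated.

## Coverage, metagene profiles and region scores

Tracks are per-base counts plus a library size; RPM normalization is
`count * 1e6 / total_mapped_reads`.  Internally coordinates are 0-based;
offset 0 is the TSS base, windows are inclusive at both ends (so ±1 kb
spans 2001 bases).  Profiles are strand-aware: minus-strand windows are
reversed so positive offsets always mean downstream of transcription.

An *average TSS* profile is ambiguous between averaging profiles across
transcript anchors and constructing one averaged TSS coordinate per
gene.  We implement the former (`all_tss`) — occupancy is assessed around the
TSSs of all annotated transcripts — plus the
alternative anchoring at the TSS with the highest promoter Pol II
occupancy (`max_polII_tss`, ranked by summed RPM over ±300 bp — the same
window the traveling ratio uses, for internal consistency).  The averaged
coordinate variant is deliberately not implemented.

Anchors whose window would overrun a chromosome end are dropped and
counted, not zero-padded: padding would fabricate boundary dips in mean
profiles.  Per-offset aggregation across anchors uses the mean (profiles here are
mean-RPM summaries), not the median.  Region scores sum
oriented RPM over a window (default ±1 kb; ±4 kb profile window for
H3K27me3, whose domains are broad); in `all_tss` mode a gene's score is
the mean of its transcripts' sums.  Conditions are compared by the
Wilcoxon rank-sum test with midranks; the p-value is exact by full
enumeration when $n + m \le 12$ without ties, and otherwise a normal
approximation with tie and continuity corrections (delegated to
`stats::wilcox.test`, which implements exactly this contract).

## Traveling ratio

$\mathrm{TR} = b/p$ where $p$ is the set-level mean of per-gene summed RPM
over promoter offsets $-300..+300$ (601 bp) and $b$ over body offsets
$+301..+2250$ (1950 bp).  Stating the body window as 0.3–2.25 kb past the TSS leaves open which
window owns the shared boundary base; we assign $+300$ to the promoter
so the windows partition cleanly.  The ratio
is of set-level means (each gene first averages its transcripts'
summed RPM, then the set averages its genes), not a mean of per-gene
ratios, which would be a noisier and different statistic.  TRs are reported per condition and normalized to the
resting state.  A zero promoter mean is an explicit error, never a silent
infinity.  Transcripts whose body window runs past the annotated gene end
are truncated there by default (and counted); configurable, since excluding
short genes instead would be an equally defensible convention.

Uniform coverage gives the closed form $\mathrm{TR} = 1950/601 \approx
3.2446$, which the tests assert to machine precision, along with
invariance under count scaling (the RPM factor cancels in the ratio).

## Motif enrichment

The enrichment step is self-contained by design: an external
motif-enrichment binary would make the pipeline unreproducible in
isolation, so a documented equivalent is implemented instead — log-odds
PWM scanning plus a cumulative hypergeometric test (which is also the
default enrichment statistic of the usual promoter-motif tools).
Equivalence with any specific external tool is not claimed.

Scanning scores $\sum_j \log_2 (p_{j,b}/0.25)$ at every offset on both
strands, with matrix probabilities floored at $10^{-3}$ before the log so
sharp matrices cannot produce $-\infty$.  A hit is a window scoring at
least `score_fraction` (default 0.8) of the motif's maximum attainable
score — an openly stated tunable of this implementation.  Windows containing N are skipped.  Promoters are counted ZOOPS
(zero-or-one occurrence per sequence), and the test is the upper-tail
hypergeometric: drawing `fg_total` promoters from the pooled collection,
the probability of at least the observed number of hit-promoters.  The
background set is the promoters of unchanged genes.
Top-$k$ lists (default $k = 30$) order by p-value with ties broken by
larger foreground hit count, then motif id — a deterministic order so runs
are reproducible.

The inner scan loop is C++ (via Rcpp), as scanning a few hundred 2-kb
promoters with ~80 matrices in pure R would dominate the pipeline's run
time.

## miRNA categories and CpG proximity

miRNAs reuse the same fold-change and twofold-call primitives as mRNA
(same pseudocount, same boundary conventions) but apply only the plain
twofold rule — the two-to-fourfold preferential band is an mRNA-only
rule.  The direction pair maps onto nine categories,
including the two opposing-direction sets.  No minimum-abundance filter is
applied by default (the emulated design states none); the pseudocount already damps folds
of barely-expressed miRNAs.

A promoter is CpG-associated when its TSS lies inside a predicted island
or within 200 bp of the nearest island edge, boundary-inclusive, with BED
half-open interval conventions; the distance is a gap count, so merging
overlapping islands can never change a call.  Distance is measured from
the TSS point, not by whole-promoter overlap (the usual phrasing of the rule is
TSS-centric).  A TSS on a chromosome without islands gets infinite
distance.  The hinted H3K27me3 × CpG relationship is exposed only as the
joined calls table; no test is attached to it.

## The synthetic-data generator

The generator is the package's stand-in for the deposited sequencing data;
its defaults are the study conditions every test and the acceptance script
run under.

**Coverage** is drawn per base pair as Poisson counts around an expected
RPM profile, not by simulating and aligning reads: alignment is out of
scope, and RPM-level profiling consumes exactly the per-base intensity
that the Poisson model provides.  Expected profiles: Pol II is a Gaussian
promoter peak (height 4 RPM/bp at the dominant TSS, SD 150 bp) plus a
uniform body density (0.5 RPM/bp at rest) spanning oriented offsets
+301..gene end — the body starts past the pause region, so the promoter
and body windows partition exactly and planted body:promoter manipulations
map linearly onto TR; H3K4me3 is two Gaussians at offsets −300/+500 (SD
200 bp, upstream peak at 70% height), the classic bimodal flank around a
nucleosome-depleted region; H3K27me3 is a uniform domain of half-width
3 kb; everything sits on a 0.02 RPM/bp background.  Condition effects are
per-class multipliers encoding the study's signatures: BCR raises promoter
Pol II (globally, most at BCR-preferential genes) with little body gain;
LPS raises body occupancy; H3K4me3 rises under both stimuli but more under
LPS; H3K27me3 falls around the TSS under BCR and barely moves under LPS.
Library sizes default to the study's reported mapped-read totals (e.g.
Pol II 18.1/14.2/21.3 million for rest/BCR/LPS).

**Genes** (382 by default) sit on one chromosome with 6-kb bodies and 6-kb
flanks (≥ 5 kb is enforced so every window fits), strands alternating
within each class.  Class sizes scale the study down: 180 shared-induced
vs. 10 + 10 preferential (~90% shared), 130 unchanged (~1/10 of the
study's 1315), and small decreased sets.  Each gene gets 1–3 transcripts;
secondary TSSs are jittered by 100–200 bp.  The jitter ceiling (200 bp)
matches the scale of TSS ambiguity the anchoring modes are meant to
absorb; the 100-bp floor is a generator choice — below it the dominant and
secondary anchors become statistically indistinguishable at realistic
depth, which would make dominant-TSS recovery an ill-posed target rather
than a property worth testing.

**Expression and miRNA tables** are negative binomial around
`baseline × fold`, with log-normal baselines and planted per-class folds
(induced 4× or 8×, preferential pairs like (8, 1), decreased reciprocals).
Dispersion defaults to 0.01 (CV ≈ 10%, deep-coverage technical noise): the
twofold rule on single tracks presupposes measurement noise well below
twofold, and a dispersion that routinely pushes unchanged genes across the
threshold would contradict the design being emulated.  Dispersion 0 gives
noise-free tables equal to their expectations, which the exact-recovery
tests use.  The default miRNA layout plants 60 changed miRNAs among 120,
with 20 LPS-increased and 29 BCR-decreased among the single-response sets
— the study's headline composition.

**Motifs** are planted as exact consensus occurrences (length 10, matrix
probability 0.97 at the consensus base) at uniform random offsets and
strands within the −1000/+1000 promoter, at rate 0.5 per promoter in a
motif's target classes and 0.05 elsewhere; overlapping plants within a
promoter are dropped.  Motifs come in families: 30 target the shared set,
of which 18 are also planted in BCR-preferential promoters, plus 12
BCR-unique, 30 LPS-unique and 8 never-planted decoys.  This family
structure is what such motif comparisons report in practice — each
response enriches a family of related matrices, the shared and BCR lists
overlapping heavily (18 of the top 30) and the LPS list overlapping
neither — and it is also what makes the top-30 comparison well-posed: with
a single planted motif per set, the other sets' top-30 would fill up with
statistically null motifs and would contain the focal motif by
exchangeability alone most of the time.

**CpG islands** (600–1500 bp wide) are placed so that a configurable 75%
of promoters per class are associated — 70% of those with the TSS inside
the island, the rest at a gap of 1–200 bp — so that most
promoters are CpG-associated with no preference between responses.

**Determinism.** Every component draws from its own sub-seed
(`seed + 0..5` for annotation, coverage, expression, sequence, miRNA,
CpG), so a fixed seed yields byte-identical outputs regardless of which
components are requested, and the full pipeline writes byte-identical JSON
summaries across runs.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: no read-level artifacts (mappability,
duplicates, fragment-length effects, GC bias), no library-complexity
model, no replicate structure (the emulated design has single tracks per
condition), promoter sequence is i.i.d. uniform ACGT rather than
CpG-biased genomic sequence, planted motifs are exact consensus rather
than degenerate sites, and coverage noise is Poisson around a smooth truth
rather than the heavy-tailed, peak-shifted reality of ChIP.  Tests passing
on this generator demonstrate that the procedures are implemented
correctly and recover planted structure under the stated statistical
model; they do not validate the biological conclusions on real data.

## Problem sizes

The suite and the acceptance script size their simulations for a laptop:
classification recovery uses 1000 genes (5 planted fold classes × 200,
noise-free); traveling-ratio recovery uses 60 single-TSS genes at library
size 10⁷; the motif study uses 100 promoters per set against a
100-promoter background with the 80-motif default library; determinism
runs the full pipeline twice on a 36-gene configuration at 10⁶ reads per
track.  These sizes were chosen as the smallest at which the stochastic
recovery bands (e.g. normalized TR within 10% of its planted value) are
comfortably met by the model's own sampling variance.

## Known limitations

- The classification applies fixed fold cutoffs to single tracks; there is
  no replicate-based significance testing, mirroring the emulated design.
- Pathway-level gene selection by per-gene significance testing is not
  implemented: the emulated single-track design gives such a test nothing
  to stand on.
- The motif scan's score threshold (fraction of maximum score) is a
  pragmatic hit definition, not a calibrated false-positive rate; p-values
  compare sets under identical scanning, which is what the enrichment
  contrast needs.
- CisBP/JASPAR library content is user-supplied; only the JASPAR-style
  text format is parsed.
- BigWig output, peak calling, input-subtraction and de novo CpG-island
  prediction are out of scope.
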