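---
title: "From bead fluorescence to connectivity: the cmapkit processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bead fluorescence to connectivity: the cmapkit processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapkit)
```

cmapkit implements the complete analysis stack for a bead-based targeted
transcriptional screen: a Luminex-style assay in which each bead color
carries the DNA barcode of exactly one panel gene, wells of perturbed cells
are profiled in bulk, and the downstream questions are (1) which
perturbations elicit a reproducible transcriptional response, and (2) which
reference perturbations a user-supplied expression change mimics or
reverses.  This vignette describes the processing model, the choices made
where the design was genuinely open, and what the synthetic-data generator
does and does not emulate.

## The five data levels

**Level 1 → 2 (MFI).** The raw input is one fluorescence intensity per bead.
Because the panel couples one gene per bead color (in contrast to the 2:1
duplexed 978-gene L1000 pool), no peak deconvolution is needed: the level-2
value is simply the median fluorescence intensity (MFI) across all beads of
a barcode in a well.  The median is robust to the occasional aggregated or
misclassified bead; wells with no beads for a gene propagate a missing
value.

**Level 2 → 3 (calibration + quantile normalization).** Wells differ in
lysate amount, amplification efficiency and scanner gain.  Two
normalizations address this:

1. *Invariant-set calibration.*  Each well carries a 10-level ladder of
   invariant genes whose expression is assumed stable across conditions.
   Within each well we map the median MFI of each ladder level onto its
   canonical value and apply the resulting monotone curve to all genes.
   The curve is fitted on `log2(MFI + 1)` — fluorescence spans three
   decades, and distortions are closer to affine on the log scale — as a
   piecewise-linear interpolation through the (observed median → canonical)
   points, isotonic-adjusted when the observed medians are non-monotone
   (with a warning), loess-smoothed (span 0.9, degree 1) only when at least
   7 points are available, and linearly extrapolated beyond the ladder from
   the two outermost points.  Ten points under-determine a free smoother;
   monotone interpolation is stable and preserves the calibration intent.
   Wells with fewer than two usable ladder levels cannot be calibrated and
   are flagged failed-QC; `process_screen()` excludes them and reports the
   count.  The canonical ladder values default to a geometric ladder
   `2^6 … 2^15`.  Their absolute scale is immaterial — only the monotone
   mapping matters — so they are configurable but rarely worth changing.

2. *Per-plate quantile normalization.*  All wells of one detection plate are
   then forced to a common empirical distribution, the mean of the plate's
   sorted columns (ties receive the mean of their target quantiles, via
   `limma::normalizeQuantiles`).  The plate — not the whole screen — is the
   normalization unit because optical and batch effects are plate-scoped.

**Level 3 → 4 (robust z).** For each gene, z = (x − median) / (1.4826 ×
MAD), with median and MAD taken across *all* samples of the same plate.
Treated wells are included in the reference distribution: any one gene is
perturbed by only a small minority of compounds, so the plate median is a
robust null, and excluding treated wells would require knowing the answer
in advance.  The constant 1.4826 makes the MAD a consistent estimator of a
normal standard deviation; the MAD is floored at 1e−6 and genes constant
across a plate are defined to have z = 0 rather than 0/0.

**Level 4 → 5 (MODZ collapse).** Biological replicates (same perturbagen,
cell line, dose, time) are collapsed by a weighted average in which each
replicate's weight is its mean Spearman correlation to the other
replicates, clipped below at 0.01 and normalized to sum to one.  Outlier
replicates are thereby down-weighted without being discarded.  With one
replicate the collapse is the identity; with two, the weights are
necessarily equal and the collapse is the arithmetic mean.  Spearman
correlations use all panel genes with average-rank ties and pairwise
deletion of missing values — the panel is small (hundreds of genes), so no
landmark subset is needed.

## Signature quality metrics

* **CC (replicate correlation):** the 75th percentile
  (linear-interpolation quantile) of all pairwise Spearman correlations
  among the level-4 replicate profiles.  A single replicate has no pairs;
  CC is then defined as 0 — absence of evidence of consistency.
* **SS (signature strength):** the number of panel genes whose moderated
  z-score exceeds 2 in absolute value (strictly), with
  Za = mean(z) × √n.  The √n moderation means Za behaves like a
  one-sample z statistic: under the null its variance is 1 regardless of
  the replicate count, so SS is comparable across replicate designs.
* **TAS (transcriptional activity score):**
  √(SS × max(CC, 0) / G), with G the panel size (467 for the neuronal
  panel).  TAS combines magnitude (SS) and consistency (CC) on [0, 1]; the
  clamp at 0 means anti-correlated replicates contribute no activity, and
  the square root places the conventional activity threshold (0.212) in a
  useful part of the scale.  Both the √n moderation and the square root are
  exposed as flags (`moderated`, `sqrt_scale`) because the unmoderated /
  unrooted variants appear in older processing stacks.

The SS of a replicate set is computed from the per-replicate mean z rather
than from the collapsed level-5 vector; the two coincide when collapse
weights are equal and differ negligibly otherwise.

## The connectivity query engine

A query is a pair of disjoint gene lists (up, down), typically the top 137
positive and top 150 negative log2-fold-change genes of a differential
expression analysis (sizes bounded by default to [10, 150] per list).
Against each reference signature, ranked by descending z:

* **WTCS.**  ES_up and ES_down are weighted Kolmogorov–Smirnov enrichment
  scores (hit increments proportional to |z|, the GSEA weight-1 convention;
  miss decrements 1/#misses; score = the running-sum extremum).
  WTCS = (ES_up − ES_down)/2 when the two scores disagree in sign and 0
  otherwise — a query whose up and down lists fall on the same flank of the
  signature is incoherent, not connected.
* **NCS.**  WTCS values are normalized by the mean |WTCS| of same-signed
  scores within each (cell line, perturbagen type) stratum, so that "strong
  for a compound in this cell line" is measured against that stratum's own
  score scale.
* **tau.**  The signed percentile of |NCS| against a touchstone background
  of the same cell line: tau = sign(NCS) × 100 × fraction of background
  |NCS| *strictly* smaller.  tau ∈ [−100, 100]; +100 is a stronger positive
  connection than everything in the reference, i.e. a mimic; −100 a
  reversal.  By default the background is the query's own NCS distribution
  within the cell line (self-contained and always available); an external
  background can be supplied when a fixed touchstone collection exists.
* **Median tau** across cell lines summarizes each perturbagen; descending
  order gives the mimic ranking, ascending the reversers (top-25 flags by
  default).  Even-count medians are the midpoint of the central pair.

Strictness conventions (strict `>` in SS, strictly-smaller in tau's
percentile, ties in similarity rankings broken lexicographically by
perturbagen id) are fixed so that identical inputs give identical outputs.

## Recall validation

Probe fidelity is validated by correlating each probe's measurements across
a panel of reference cell lines with every gene of a reference RNA-seq
matrix (log2 RPKM): the *recall rank* of a probe is the percentage of
reference genes correlating strictly higher than the probe's matched gene,
and a probe passes at rank < 5%.  Probes whose matched gene is absent from
the reference, or constant in either matrix, have no defined rank and are
excluded from the denominator — which is why an analyzed set can be smaller
than the panel.  Failed probes are annotated as lowly expressed when their
reference mean log2 RPKM falls below 1 (configurable; the criterion is
qualitative).  Rank correlations make the report invariant to monotone
transforms of either matrix.

Whole-signature recall follows the same logic one level up: a test
signature passes the activity gate at TAS ≥ 0.212, its Spearman
correlations to a reference collection are ranked, and the matched
compound's best rank is compared to a threshold (default 190, the ~10% cut
of a 1,886-signature reference).  Inactive signatures are reported but not
evaluated for recall.

## The synthetic screen generator

`simulate_screen()` draws bead fluorescence as
`2^(baseline + cell-line offset + planted effect + well noise) `, passes
each well through a monotone affine distortion on the log2 scale — which
the invariant calibration must undo — and adds log-normal bead noise.  Its
defaults are the study conditions of a full screen: 6 cell lines × 60
compounds × 2 doses (0.5 and 5 uM, the high dose scaling the effect 1.5×)
× 3 replicates, a 467-gene panel with an 80-probe invariant ladder, one
384-well plate per cell line including 24 vehicle wells, 3 beads per gene
per well, 80% of compounds active on random 20-gene modules at 4 z-units.
Noise defaults (bead sd 0.2, well sd 0.1, cell-line offset sd 0.3, all
log2) were chosen so that a vehicle well's profile is realistically noisy
but a 4z planted effect is comfortably detectable — the regime a functioning
screen operates in.  Planted effects are specified in robust-z units and
converted to log2 shifts through the implied per-gene plate standard
deviation √(well_sd² + bead_sd²/n_beads), so "a 4z effect" means 4 plate
standard deviations *before* calibration error; recovered z-scores are
accordingly slightly smaller.

The generator emulates: bead-count variation in the median, per-well affine
distortions, dose-scaled module effects, vehicle wells with no effect, and
(via companion generators) reference RNA-seq panels with a target
probe/reference correlation and touchstone signature collections with
optional planted knockdowns sharing a compound's module.  It does **not**
emulate: saturation or optical cross-talk of a real scanner, bead dropout
correlated with expression, compound toxicity (global profile collapse), or
correlated gene-gene covariance within modules.  Passing tests therefore
demonstrate correctness of the statistical machinery under a faithful null
and a detectable alternative — not performance on any real screen.

## Numerical and scale choices

* Calibration targets `log2(canonical + 1)` so that an undistorted well is
  reproduced exactly (identity curve), and outputs are returned on the
  fluorescence scale (`2^y − 1`).
* Missing values propagate through levels 2–3 and are excluded pairwise
  from medians and correlations; GCT files store them as `NaN` tokens and
  read back as `NA`.
* The 2-D embedding of signatures is an exact (O(n²)) t-SNE with
  deterministic PCA initialization, perplexity capped at (n−1)/3, learning
  rate 100 and early exaggeration 4 — screen-scale collections are hundreds
  of points, where aggressive optimizer settings destabilize the layout.
  Exactly duplicated signatures are embedded once and share coordinates:
  t-SNE's attraction does not reliably merge duplicates at small n, and
  coincident points are the only faithful representation of identical
  inputs.
* Test and validation problem sizes (e.g. 12-compound null screens on the
  full 467-gene panel, 500-probe recall references with 2,000 decoys, 200
  random null queries) were sized to make the binomial/KS tolerances of the
  checks meaningful while keeping a full validation run in minutes on one
  core.

## Known limitations

* The invariant calibration assumes at least two usable ladder levels per
  well and monotone distortion; pathological non-monotone distortions are
  isotonized, which flattens genuine signal in the affected range.
* NCS stratification uses (cell line, perturbagen type); finer stratification
  (e.g. by time point) is a caller decision via the metadata columns.
* Query genes absent from the measured panel are dropped with a logged
  count; no imputation of unmeasured genes is attempted.
* The self-contained tau background (the query's own NCS distribution)
  makes tau a within-query percentile; cross-query comparability requires
  an external touchstone background, which the API accepts but does not
  fabricate.
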