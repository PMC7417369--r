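---
title: "Computational cytometry of developing thymocytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational cytometry of developing thymocytes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thymoflow)
```

# The problem

Multi-colour flow cytometry of the paediatric thymus produces millions of
events per staining panel, across dozens of donors acquired on different
days. Conventional analysis draws a fixed tree of two-dimensional gates per
sample, which scales poorly, cannot borrow strength across samples, and
struggles with populations that transition gradually (e.g. CD1a-graded
maturation of single-positive T cells) or that are rare (plasmacytoid
dendritic cells at ~0.2% of mononuclear cells). thymoflow implements the
alternative that single-cell transcriptomics made standard: pool all
samples of a panel, subsample to a tractable size, correct acquisition-day
batch effects, build a k-nearest-neighbour graph, partition it with the
Leiden algorithm, and map clusters back to named immune populations whose
per-sample frequencies can then be tested against donor age.

Every stage is exercised end-to-end on a synthetic-cytometry cohort with
planted ground truth, so the package's guarantees are stated as recovery
properties, not appeals to plausibility.

# Preprocessing model

**Compensation.** Fluorescence detectors leak into one another linearly:
with spillover matrix $S$ (rows = source channels, unit diagonal), observed
intensities are $x_{obs} = x_{true} S$. `compensate()` applies
$x_{obs} S^{-1}$, the exact inverse; scatter channels pass through. The
convention (rows = source, as in the FCS `$SPILLOVER` keyword) is fixed and
documented because the transposed convention is also in circulation.

**Logicle transform.** `logicle()` implements the biexponential display
scale of Parks–Roederer–Moore: a strictly increasing map, logarithmic at
high intensity and linear around zero, parameterised by top of scale $T$
(fluorescence units), linearisation width $W$ (decades), total decades $M$
and extra negative decades $A$. The forward biexponential
$x(y) = a e^{by} - c e^{-dy} - f$ has closed-form coefficients derived from
$(T, W, M, A)$; the transform inverts it by vectorised bracketed bisection
driven to machine precision, so `logicle_inverse(logicle(x)) = x` far
inside the `1e-6 * T` contract. Defaults are $T = 262144$, $W = 0.5$,
$M = 4.5$, $A = 0$ — the fixed defaults of the transform's reference
implementation; they are configurable per channel. Fixed points worth
remembering: `logicle(0) = W + A` and `logicle(T) = M`.

**Gating.** Gates are declarative rectangles applied in order
(`apply_gates()`), reproducing a manual sequential gating tree with
per-gate removal counts for logging. Presets cover the standard exclusion
series — singlets on FSC-W/SSC-W, debris on FSC-A/SSC-A, a lineage dump
channel, CD45 or CD3/TCRgd selection — with scatter bounds in raw units
and fluorescence bounds in decades (gates are applied after the
transform).

**Pooling and standardization.** All samples of a panel are concatenated
and the retained marker subset is z-scored with a single global mean and a
population (divide-by-$n$) standard deviation per column, so that distances
weight markers equally. Scatter channels, which are never
logicle-transformed, are first min-max scaled onto $[0, M]$ to make their
spread commensurate with transformed fluorescence before z-scoring. The
retained subsets per panel mirror the five staining panels of the default
design (`panel_retained_markers()`).

# Subsampling

Two reduction schemes, used together by default (a 50:50 split of the
budget, `combined_subsample()`):

* `random_subsample()` — uniform without replacement, stratified so each
  sample contributes proportionally (largest-remainder apportionment).
  Unbiased for population frequencies; used as the denominator for all
  frequency statistics.
* `geometric_sketch()` — a grid-cover sketch: project to principal
  components (all marker dimensions by default, since panels retain at most
  eight), min-max scale to the unit hypercube, binary-search a common box
  side length until the number of occupied boxes approximates the target
  (within 2% or 40 iterations, ties toward fewer boxes), then sample one
  event from each chosen box. Box occupancy, not abundance, drives
  selection, so rare but geometrically distinct populations are strongly
  enriched (the planted 0.2% population typically gains ~9-fold at a 10%
  sketch) while frequencies are deliberately distorted — which is why the
  sketch feeds clustering but never frequency estimation.

Both samplers are deterministic given a seed and equivariant under
permutation of the input rows: selection keys attach to event content
(events are ranked canonically by their coordinates before seeded draws),
not to row positions.

`assess_subsampling_bias()` quantifies the distortion without using planted
truth: per sample, events are split into 10 equal random bins, each bin is
clustered by k-means into groups of ~500 cells, and the resulting reference
clusters' frequencies before and after subsampling are compared by the
coefficient of determination of a linear fit. The binning criterion ("10
equal bins") is by event count with seeded random assignment, and the
reference clustering runs per sample; both choices were open and are fixed
here. k-means stands in for a mini-batch variant because bins are a few
thousand events at most, where batching changes nothing. A 50% random
subsample of a 10^5-event cohort scores R² ≈ 0.995.

# Batch correction

Acquisition day is the technical batch. `regress_out_batch()` fits, for
each standardized marker independently, ordinary least squares on an
intercept plus reference-coded batch indicators (via limma's `lmFit` /
`residuals.MArrayLM`) and keeps the residuals. Consequences that the tests
pin down: per-batch marker means are exactly equal afterwards (to ~1e-14),
residuals are orthogonal to the design, and the operation is idempotent.
Residuals are *not* re-standardized by default (a flag restores unit
variance), matching the ordering transform → z-score → correct → graph.

Two modelling caveats are deliberate:

* Only additive structure on the standardized scale is removable. The
  synthetic generator therefore plants day effects dominated by detector
  gain drift (±8%), which the logicle turns into near-uniform decade shifts
  on positive populations — exactly the additive structure the model
  removes — plus a small baseline drift (±50 raw units) that fans out
  negative populations and leaves a small, honest residual.
* Biological covariates are excluded from the design. If batch is
  associated with the 1.5-year age grouping at the sample level (Fisher
  test, p < 0.05), a warning flags that correction may absorb age-related
  biology.

# Graph clustering

`build_knn_graph()` computes exact Euclidean k-nearest neighbours (kd-tree)
and converts distances to fuzzy simplicial-set connectivities: per event,
$\rho_i$ is the nearest-neighbour distance and $\sigma_i$ is calibrated by
bisection so the smoothed weights $\exp(-(d_{ij} - \rho_i)/\sigma_i)$ sum
to $\log_2 k$; the directed weights are symmetrised by the probabilistic
union $w = a + b - ab$. Each event's nearest-neighbour edge has weight 1.
`k = 15` by default (the neighbourhood convention of the UMAP toolchain);
per-round override available.

`leiden_partition()` maximises the resolution-parameterised
(RB-configuration) quality
$Q(\gamma) = \sum_c \left( e_c - \gamma K_c^2 / 2m \right)$
on the symmetrised weighted graph. The optimiser is igraph's Leiden
implementation with the modularity objective, whose quality equals
$Q/2m$ — the same argmax; the quality function itself (`rb_quality()`) is
implemented in-package and backs the invariant tests. Cluster ids are
ordered by decreasing size; runs are deterministic given a seed.

One behaviour deserves emphasis because it shapes the whole design: at the
default $\gamma = 1$, modularity's resolution limit sub-divides large
homogeneous populations into several clusters. These sub-clusters are pure
(they never mix planted populations), and the cluster→population annotation
step merges them, so population recovery is unaffected; a lower resolution
(γ ≲ 0.2 on the synthetic blobs) recovers the planted partition exactly if
a one-to-one clustering is wanted. The graph is symmetrised before
partitioning; a directed variant would optimise an equivalent quality on
the symmetrised weights.

`iterative_subcluster()` runs multiple rounds: each round restricts to the
events of targeted parent clusters, rebuilds the graph on that round's
marker subset (e.g. including CD44 while excluding CD34 to split committed
from uncommitted progenitors), re-partitions, and records `parent/child`
lineage paths. Untargeted events keep their labels verbatim.

`umap_embed()` produces the 2-D reporting embedding (seeded,
single-threaded); clustering never reads the coordinates.
`cluster_profiles()` summarises clusters by per-marker medians of the
*transformed* (not z-scored) intensities plus a per-marker min-max scaled
copy — the scaled-MFI heatmap that drives annotation.

# Annotation and label transfer

`annotate_clusters()` maps each cluster to the unique rule whose hi/lo/mid
constraints its scaled profile satisfies ("unassigned" if none; an error
naming the rules if several — overlapping rules are a configuration bug,
not a data property). Preset rule sets encode each default panel's
populations; thresholds (hi ≥ 0.7, lo ≤ 0.3, CD1a-high ≥ 0.85 vs the
0.3–0.85 mid band) sit in the wide gaps between the generator's expression
levels. Min-max profile scaling needs both ends of each marker represented
among the clusters, so for very small runs the majority-overlap mapping
(each cluster → reference label of maximal overlap, ties toward the larger
class) is the robust fallback and the pipeline's default benchmark mapping.

`fit_transfer()` transfers subpopulation structure across developmental
branches — the motivating case being CD1a-graded maturation learned on
SP CD8b+ cells and applied to SP CD4+ cells — with L2-regularized
multinomial logistic regression (glmnet ridge; the inverse regularization
strength C maps to `lambda = 1/(n*C)`). The C grid
{0.01, 0.1, 1, 10, 100} is searched by stratified k-fold cross-validated
accuracy (5 folds, seeded splits, ties toward stronger regularization),
then the model is refit on all training data. The feature set excludes the
branch-defining markers (CD4, CD8b) by default, so the classifier cannot
lean on the covariate that shifts between branches; the tests require
cross-branch accuracy within 2 points of same-branch accuracy.
`predict_and_score()` reports per-class one-vs-rest confusion counts with
accuracy $(TP+TN)/(TP+TN+FN+FP)$, sensitivity $TP/(TP+FN)$ and specificity
$TN/(TN+FP)$; 0/0 ratios raise rather than silently returning NaN (a
per-class skip flag exists).

# Population statistics

`population_frequencies()` counts per-sample fractions against an optional
nested denominator (all events, CD45+, CD3+TCRgd+, ...). In the pipeline,
frequencies are computed from the random-origin events only, because the
sketch is enriched by design.

`f_measure_report()` benchmarks candidate labels against a reference
(planted truth here; manual gates in real data): one-vs-rest precision,
recall, and their harmonic mean F, per sample and population; a population
the candidate never predicts scores F = 0, and populations absent from both
sides are omitted. The implementation is cross-checked in the tests against
an independent confusion-matrix oracle and against caret's
precision/recall mode.

`group_difference_test()` fits, per population, OLS of per-sample frequency
on the age-group indicator (older vs younger than the 548-day breakpoint)
plus batch indicators, tests the group coefficient two-sided, and adjusts
p-values jointly across populations. Benjamini–Hochberg is the default
adjustment (the reported quantities are q-values); Holm — R's `p.adjust`
default — and Bonferroni are available, a divergence documented here.
Frequencies enter untransformed. Rank-deficient designs (group confounded
with batch) are an error naming the collinearity, not a silent drop.
Calibration is tested, not assumed: over 1000 null cohorts drawn from the
generator's sampling model the type-I error at α = 0.05 lies within
[0.035, 0.065], and power for the planted +0.02 B-cell step at n = 26
exceeds 0.8 (in practice ≈ 1).

`paired_population_test()` is the classical paired t; `loess_trend()` fits
the tricube local polynomial (span 1, degree 2 — the fitting function's
convention — both configurable) of frequency against log2 age for the
trend figures.

# The synthetic cohort generator

`build_default_thymus_spec()` encodes the study-shaped conditions:

* five panels whose retained marker sets are the CD34-progenitor panel
  (CD34, CD44, CD7, CD5, CD123), monocyte/macrophage (CD14, CD16, HLA-DR
  + scatter), B-cell/DC (CX3CR1, HLA-DR, CD19, CD1c, CD123 + scatter),
  gamma-delta (TCRgd, Vg9, Vd1, Vd2 + scatter) and alpha-beta
  (CD4, CD8b, TCRab, CD3, CD69, CD1a, CD28);
* 26 MNC and 35 CD34-enriched samples on a log2-day age grid from 1 to
  5110 days (birth to 14 years), acquired in 5 round-robin batches;
* ≥ 10 alpha-beta populations including the CD1a hi/lo maturation split, a
  0.2% plasmacytoid-DC population, and a +0.02 B-cell frequency step for
  donors older than 1.5 years (548 days);
* 3% doublets (random event-pair sums with FSC-W widened 1.8×), 5% debris
  (low scatter), a banded spillover matrix (3% bleed into the adjacent
  channel), and per-sample logit-normal frequency jitter (sd 0.15) for
  between-donor variability.

Population intensities are Gaussian on the logicle scale and mapped to raw
by the inverse biexponential, so gates drawn on biexponential axes agree
with the truth by construction. Per-sample seeds are hashed from the master
seed and sample index, so any sample regenerates in isolation and cohorts
are bit-reproducible. Real per-population frequencies are not published for
this design; the defaults are plausible placeholders chosen once, with only
their qualitative features (rarity of pDC, dominance of DP thymocytes, the
B-cell step) treated as meaningful.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: populations are well-separated Gaussian modes
rather than smears with heavy tails and gradual continua; spillover is
small and banded rather than panel-wide; batch effects follow the
gain-plus-baseline model exactly; and marker levels are discrete. Recovery
results on this cohort validate the machinery (the pipeline finds what is
planted, at the planted rarity, despite the planted artifacts), not the
biology of any particular tissue.

# Numerical and reproducibility choices

* Logicle bisection: 100 halvings on the normalised scale (~1e-17
  bracket), brackets auto-expanded for out-of-range values.
* z-scoring uses population (n) variance; tolerance 1e-8 in the contracts.
* Sigma calibration in the fuzzy graph: 64 bisection steps to a 1e-6
  target tolerance.
* All randomness flows through `derive_seed(master, ...)` (a 32-bit
  multiplicative hash); no stage consumes global RNG state, and
  `run_pipeline()` re-run with the same config is byte-identical, UMAP
  included.
* Degenerate inputs have defined behaviour: singular spillover, zero
  variance markers, empty denominators, zero-variance paired differences
  and 0/0 confusion ratios raise descriptive errors; sub-500-event bias
  bins clamp k to 1 with a warning; the bias R² of an identity subsample
  with equal reference frequencies is defined as 1.
* Problem sizes in the shipped tests and acceptance script — 26 samples ×
  4000 events with 5 × 10^4 clustered events for recovery, ~10^5 pooled
  events for subsampling fidelity, 1000 null cohorts for calibration —
  were chosen as the smallest scales at which the planted 0.2% population
  and the frequency statistics are meaningfully exercised.

# Known limitations

* FCS support is list-mode `$DATATYPE` F/D, single data segment; FlowJo
  workspace XML is out of scope (gates are declarative config).
* Only additive (post-transform) batch structure is removed; strong
  baseline drift on negative populations survives correction and is
  visible in MFI profiles, which are computed on uncorrected transformed
  intensities.
* Annotation rules assume every population is represented among the
  clusters; small runs should use the majority-overlap mapping.
* The Leiden optimiser is delegated to igraph; only the quality function
  and graph construction are in-package.
* Frequencies are analysed untransformed; near-zero frequencies make the
  Gaussian OLS approximation rough, which the calibration test bounds but
  does not eliminate.
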