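---
title: "Methods: models, parameters and design choices in rumicol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in rumicol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumicol)
```

# Scope

`rumicol` analyses successional microbial colonization of forage particles in
rumen-simulation (Rusitec) experiments with a 2 x 2 factorial design — forage
type (fresh grass GRA vs. hay HAY) crossed with vitamin E supplementation
(-/+) — sampled repeatedly at 0, 2, 4, 8, 24 and 48 h post-feeding in four
fermentation vessels per treatment, each inoculated from a different donor
animal. Five analysis families are covered: ^15^N tracer partitioning of
plant-residue nitrogen, alpha/beta diversity of genus or OTU count tables,
distance-based multivariate testing (PERMANOVA, CCA, PCoA), time-stratified
Spearman co-occurrence networks, and FTIR metabolome fingerprints. A
synthetic-data generator reproduces the statistical structure of such an
experiment so that every stage is testable without any external download.

# Tracer model

Enrichments are atom% ^15^N excess above background; background subtraction
and natural-abundance correction are assumed to have happened upstream. Two
ratios drive everything:

* microbial fraction of residue N:
  `m = residue enrichment / SAB pellet enrichment`
* ammonia-derived fraction of microbial N:
  `a = SAB pellet enrichment / ammonia pool enrichment`

Both are plain two-pool mixing ratios; no multi-source mixing model is
attempted. Measurement noise can push `m` above 1; the package reports such
values as-is with a `flagged` attribute (clamping is opt-in) because silently
truncated fractions hide evidence of measurement error. Interval colonization
rates are first differences `Δm/Δt` (per hour), and intervals are labelled by
the tri-phasic convention: primary (≤ 2 h), secondary (2–8 h], tertiary
(> 8 h), using the interval's upper bound.

When the SAB pellet is harvested only once per vessel (the usual practice:
the pellet comes from the end of the incubation), the vessel's single
measured SAB enrichment is applied to all its time points; the output records
per vessel whether a per-time or pooled SAB enrichment was used.

# Synthetic data: the stated world

`simulate_counts()` uses a logistic-normal multinomial: latent log-abundances
are multivariate normal, softmax-transformed, and sampled multinomially at a
depth drawn uniformly from `depth_range` (default 11,265–30,000 reads; the
lower bound is the canonical depth to which real libraries were rarefied).
Defaults are the experiment's stated design: 2 forages x 2 vitamin-E levels
x 4 vessels x 6 time points = 96 samples, 120 genera.

Correlation blocks are planted with a per-block single-factor model: member
`j` gets loading `s_j * sqrt(|rho|)` on a shared factor, with alternating
signs `s_j` for negative blocks; this keeps the implied covariance positive
definite at any `|rho| < 1`, which a dense negative correlation block would
not be. A consequence worth knowing: inside a "negative" block, members with
the same loading sign correlate *positively* — the ground-truth edge list in
`SyntheticTruth` records the sign of every implied pair.

Inoculum-donor structure is a latent shift on a random ~10% subset of taxa
(sd 0.5), drawn *outside* planted blocks. Two reasons: a shift common to all
taxa cancels exactly in the softmax and would be dead weight, and overlaying
donor shifts on block members would silently change the delivered block
correlation away from the declared `rho`.

## Colonization curve family

The tracer examples require the default GRA curve to pass exactly through
the canonical fractions 0.16, 0.28, 0.42 at 2, 4, 8 h and 0.61 at 48 h
(HAY: 0.09, 0.14, 0.17, 0.61). A 3-parameter logistic cannot interpolate
four anchors, so the default family is a monotone piecewise-linear
interpolator through those anchors (constant beyond the last anchor); a
scaled logistic with per-forage rate and lag remains available via
`colonization_params = list(type = "logistic", m_max, rate, lag)`. Curves
are validated to be nondecreasing and within [0, 1].

## Covariates and spectra

Fermentation covariates follow fixed baseline curves — ammonia and lactate
peak 2–4 h post-feeding (log-normal bumps), total VFA saturate, pH dips
reciprocally — plus optional linear couplings to standardized latent taxa
and Gaussian noise (default sd 0.1). FTIR spectra live on the fixed
4000→600 cm^-1^ grid at 2 cm^-1^ steps: a smooth baseline plus Gaussian
peaks at canonical band positions (2920, 1735, 1650, 1540, 1240,
1030 cm^-1^); the carbohydrate band at 1030 cm^-1^ shrinks with colonization
m(t) (substrate consumption), treatment contrasts multiply chosen peak
amplitudes, and absorbance noise defaults to 0.002 AU.

What the generator does *not* emulate: read-level sequencing error and
chimeras, taxon-specific sequencing bias, compositional zero-inflation
beyond the multinomial, donor-by-treatment interactions, and instrument
drift in spectra. A green recovery test therefore establishes correctness of
the estimators under the declared statistical structure, not robustness to
every artefact of real data.

All randomness flows from one config seed; sub-stages use fixed small
offsets of it (counts +0, covariates +1, spectra +2, enrichment +3), so one
seed determines the entire bundle bit-for-bit.

# Community statistics

Rarefaction is one without-replacement draw per sample (hypergeometric), not
an average over repeated draws, matching the "normalize to the lowest read
count" convention. Shannon uses natural log; Simpson is reported as
Gini–Simpson `1 - sum(p^2)` (larger = more diverse) with the raw dominance
also emitted; Chao1 switches to the bias-corrected form `S + F1(F1-1)/2`
when no doubletons exist, flagged per sample. Bray–Curtis can be computed on
raw or relative counts; the choice is recorded on the result. UPGMA is
average-linkage `hclust` with Newick export (branch lengths are half merge
heights, so cophenetic distances reproduce ultrametric inputs exactly).

Per-taxon differential abundance tests log10 relative abundance with a
pseudocount of 1 read added before the transform. The univariate test is a
permutation test (mean difference for two groups, one-way F for more) —
the source analysis did not name its univariate test, so this substitution
is deliberate and documented. FDR control is hand-written
Benjamini–Hochberg step-up, verified against brute force.

# PERMANOVA

Sums of squares are partitioned on the Gower-centered matrix
`G = J(-D^2/2)J` (McArdle–Anderson), sequentially (Type I) in the order the
terms are given. The balanced factorial makes orders coincide; for
unbalanced inputs the order matters and is the caller's statement of
hypothesis. Pseudo-F per term uses the residual mean square of the full
model. Significance uses permutation of residuals under the reduced model
excluding the tested term (Freedman–Lane): with `H_r` the reduced-model hat
matrix and `P` a permutation, the permuted inner-product matrix is
`M G M'` with `M = H_r + P(I - H_r)`, and the sequential statistic is
recomputed on it. P-values use the `(b + 1)/(m + 1)` convention, so zero
p-values cannot occur. Donor can be fitted as a term, and permutations can
optionally be restricted to within-donor exchanges; the default is free
residual permutation.

The "Monte Carlo" p-value is obtained by matching mean, variance and
skewness of the permutation null to a shifted gamma (Pearson type III),
falling back to a normal when skewness is non-positive. The original
software's Monte Carlo p is proprietary, so this is an explicit,
documented approximation — exact agreement with it is not claimed.

Exact enumeration of all `n!` permutations is available for `n <= 8` and is
used to validate the sampled p-values.

# CCA

The chi-square-standardized matrix
`Qbar = diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c))` is regressed on the
covariates weighted by sample totals, and the fitted values are
eigen-decomposed (ter Braak). Total inertia is `sum(Qbar^2)`; constrained
inertia is the eigenvalue sum and can never exceed the total. Taxon scores
are chi-square-metric unit scores; the reported site WA scores are exactly
weighted averages of taxon scores. Per-variable significance permutes one
variable's values across samples and recomputes that variable's *marginal*
constrained inertia (CCA on it alone), with the same `(b+1)/(m+1)`
convention. Collinear or constant covariates are refused rather than
silently dropped.

PCoA eigen-decomposes `G`; negative eigenvalues (non-Euclidean distances)
are reported untouched, and axes are returned only for positive eigenvalues.

# Co-occurrence networks

Per (group x time) stratum — by default forage x time pooling vitamin E, so
n = 8 — the chain is: keep genera present in *strictly more than* 75% of
stratum samples (6/8 = 75% is excluded, 7/8 kept); Spearman-correlate all
remaining genus pairs on ranks of log10(relative abundance + 1e-6) (the
monotone log makes ranking invariant — the transform is kept as a recorded
no-op safeguard); retain `|rho| > 0.7` **and** BH-adjusted `p < 0.05`. The
absolute-value reading of "larger than 0.7" is deliberate: the networks
contain negative edges. BH families are per stratum, not pooled, because
networks are built per time point.

Two-sided Spearman p-values use the full exact permutation distribution for
tie-free samples of `n <= 10`, enumerated once per `n` in compiled code
(Heap's algorithm; 8! = 40,320 for the working stratum size) and cached;
ties or larger n fall back to the t approximation.

Communities come from Girvan–Newman edge-betweenness removal with the
partition of maximum modularity along the removal sequence (igraph).
A structural caveat verified during development: the global max-modularity
partition need not lie on the removal dendrogram (dangling chains are shed
as singletons before bridges fall), so exhaustive-search equivalence is
guaranteed — and tested — on block-plus-bridge graphs, the regime the
method is meant for, not on dense random graphs.

Complexity metrics per network: node count, edge counts by sign, average
neighbors `2E/N`, and the percentage of total community abundance carried by
the network's genera (summed mean relative abundance over the stratum).
Nodes are genera incident to at least one retained edge.

# FTIR chain

Replicates are averaged pointwise; the first Savitzky–Golay derivative uses
a 13-point window with an order-2 polynomial (the order is unstated in the
source description; 2 is the standard smoothing-derivative choice and is
configurable), edge points evaluated from the polynomial fitted to the
first/last full window, and the derivative scaled by the grid spacing to
absorbance per cm^-1^. Normalization is per-spectrum autoscaling to mean 0
and sd 1; the instrument-software phrasing "mean = 1, sd = 1" contradicts
"mean center", so the +1 offset is offered as an option — a pure
translation that cannot affect the distance-based tests. Group testing is
the same PERMANOVA on Euclidean distances (derivative spectra are signed,
so Bray–Curtis would be ill-defined); the source's "non-permutational"
wording is read as a typo for "permutational".

# Numerical choices and degenerate inputs

* Design-matrix rank decisions use an SVD threshold relative to the scale of
  the candidate columns, so aliased terms are detected and named instead of
  contributing numerical-noise degrees of freedom.
* `SS_total = 0` (all samples identical) yields a flagged degenerate
  PERMANOVA result, not an error.
* Constant genera are excluded from edge inference with a logged message;
  constant taxa get `p = 1` and a flag in differential abundance.
* Fractions above 1, rarefaction depth conflicts, all-zero samples and
  zero-variance spectra all fail loudly with the offending sample named.
* Tie-break in community detection is the lexicographic edge order used to
  build the graph, making partitions deterministic.

# Limitations

Compositionality-aware correlation (SparCC-type) is deliberately out of
scope; Spearman on relative abundances can pick up closure-induced edges.
The repeated-measures REML model and Fisher's LSD of the original analysis
are replaced by permutation tests throughout. The CCA implementation does
not offer partial (conditioned) models. Spectral preprocessing handles the
uniform grids produced by FTIR instruments only.
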