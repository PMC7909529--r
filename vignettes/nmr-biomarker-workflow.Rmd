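---
title: "Urine 1H-NMR biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urine 1H-NMR biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbiomark)
```

This vignette is the package's own account of its methods: what each stage
computes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The analysis problem

Urinary ¹H-NMR profiling of a two-group cohort (cases vs controls) produces,
per sample, either a full spectrum or a vector of metabolite signal areas
referenced to the TSP internal standard. The goal is a short list of
metabolites that (a) several multivariate models agree on, (b) survive
conservative univariate screening, and (c) carry high importance in the
supervised projection — followed by an honest look at how well those markers
classify, and which pathways they implicate. The package implements that
chain as composable functions plus `run_pipeline()`.

## Spectral processing

- **Referencing** (`reference_to_tsp()`): the axis is translated so the
  tallest peak in ±0.2 ppm sits at exactly 0 ppm. The apex must clear the
  window's median by 5 median absolute deviations; a flat trace is an error,
  not a silent no-op.
- **Binning** (`bin_spectrum()`): half-open buckets `[low, low + 0.02)` tile
  0.52–9.30 ppm, left-anchored at 0.52 (bucket anchoring is not standardized
  in the field; left-anchoring makes the tiling a pure function of the
  scheme). The water/urea block 4.32–6.10 ppm is excluded as one interval; a
  bucket is dropped if it overlaps the exclusion at all, the conservative
  reading. With these defaults 439 buckets are tiled, 89 excluded, 350
  retained. Bucket areas are trapezoidal integrals on the native grid with
  exact splitting of edge segments, so binning conserves area to machine
  precision (tested at 1e-9 relative).
- **Quantification** (`integrate_metabolites()`): each metabolite's windows
  (±0.03 ppm around every multiplet center, about three linewidths at the
  simulator's default) are integrated and divided by the TSP area taken over
  the *same* halfwidth around 0 ppm — using equal halfwidths makes the
  Lorentzian tail losses cancel in the ratio. Negative noise integrals pass
  through unclipped; overlapping windows of different metabolites are
  warned about and both are integrated. Whether to bin before or after
  TSP scaling is not fixed by convention; both orders are available and the
  pipeline default is reference → integrate.

## Preprocessing

Missing, zero and negative entries become one fifth of the feature's minimum
positive value (`impute_missing()`, idempotent; a feature with no positive
value is an error naming it). Each sample row is divided by its geometric
mean (`normalize_geometric_mean()`) — the geometric mean is taken
**row-wise** because per-sample dilution is the dominant nuisance in urine.
The generalized log `g(x) = ln((x + sqrt(x^2 + lambda^2))/2)` stabilizes
variance while tolerating non-positive values; `lambda` defaults to the
table's global minimum positive value, a common heuristic, and both the
base (natural log) and `lambda` are exposed because neither is canonical.
Before the latent models, features are mean-centered and unit-variance
scaled by default (`autoscale()`, n−1 denominator): metabolite areas span
orders of magnitude, and comparable loading scales are what makes the
|loading| > 0.2 selection rule meaningful. Pareto scaling is available for
users who want to keep some magnitude weighting.

## Latent-variable models

PCA, PLS-DA and OPLS-DA are implemented from scratch with NIPALS so that
scores, loadings, weights and deflation are exactly the quantities the
selection rules refer to; independent oracles (the singular value
decomposition, least squares, and the PLS/OPLS equivalence) pin them down in
the tests.

Numerical choices:

- **Sign convention**: every weight/loading vector is flipped so its
  largest-magnitude entry is positive — results are reproducible across
  platforms, where the NIPALS sign is otherwise arbitrary.
- **Class coding**: a centered 0/1 dummy. All reported quantities (R²Y, Q²,
  VIP, unit-normalized loadings) are invariant to affine recodings, so the
  simplest coding wins.
- **PCA contributions** are per-component squared loadings normalized to sum
  to one, computed on the first component by default; a multi-component
  weighted variant would mix unsupervised axes of different meaning, so the
  per-component form is the default and the consensus uses its top 7.
- **Loading threshold**: the |loading| > 0.2 rule is applied to the first
  (predictive) component's loading vector normalized to unit length, because
  a threshold on unnormalized loadings would silently depend on the scaling
  mode.
- **Degenerate inputs**: constant features are centered and flagged rather
  than dropped; single-class labels, rank-exhausted component requests and
  empty orthogonal structure raise errors (or, for OPLS with genuinely no
  orthogonal variation, record a zero component so the predictive part
  reduces exactly to PLS-DA).

Cross-validated Q² uses stratified 7-fold assignment (a common chemometrics
default; the fold count is a parameter) with folds drawn deterministically
from a seed, and `Q2 = 1 − PRESS/SSY` on the centered label. The permutation
test refits the model and recomputes Q² under uniformly random label
permutations; p-values use the add-one rule, so 100 permutations floor the
p-value at 1/101 ≈ 0.0099. Both R²Y and Q² are tracked; the headline p is
on Q², the statistic that actually measures generalization. Quality gates
(PCA R²X > 0.4; R²Y and Q² > 0.5 for the supervised models) are recorded as
report flags — a screening pipeline should show its model quality, not
refuse to run.

## Univariate screening and subgroups

The Wilcoxon rank-sum test (two-sided throughout) runs exactly (enumeration)
when both samples are ≤ 12 and tie-free, otherwise with the normal
approximation including tie and continuity corrections; the cutoff balances
runtime against exactness and is configurable. Bonferroni adjustment is used
across features (`p → min(1, m·p)`), matching the conservative convention of
the screening design; FDR is deliberately not the default. Direction labels
come from the case-minus-control median difference, the robust choice for
skewed urinary areas. Because rank tests are invariant under monotone
transforms, screening after the glog transform equals screening the raw
areas. Subgroup comparisons (e.g. Gleason-score or PSA strata) use classical
one-way ANOVA with Bonferroni adjustment across features.

## Consensus, ROC and sensitivity comparison

`select_consensus()` intersects three criterion sets (two-model agreement,
Wilcoxon adjusted p < 0.01, VIP > 1) and reports Venn region counts for
both the model overlap and the criteria overlap. Loosening any threshold can
only grow the sets (tested as a monotonicity property).

ROC curves sweep thresholds over the observed scores, treat higher scores as
case-like (no automatic flipping — a marker whose AUC is below 0.5 should be
seen, not silently inverted), credit ties with 1/2 (so AUC equals the
Mann–Whitney concordance exactly), and pick the operating point by the
Youden index with ties resolved toward the lowest threshold. Panels combine
markers by least squares on the 0/1 label by default; logistic regression is
available, flags complete separation, and yields the same resubstitution AUC
for a single marker since the score is then a monotone transform. ROC is
computed by resubstitution — mirroring the small-cohort practice this
pipeline emulates — and a cross-validated mode is intentionally out of the
default path. Sensitivity between two panels is compared with the exact
McNemar binomial test on discordant case classifications at each panel's own
Youden threshold; the original analysis did not state its comparison method,
so this is a documented interpretation, not a reproduction.

## Enrichment and network

`enrich_hypergeometric()` computes the upper-tail (at-least-k)
hypergeometric probability per pathway, tests only pathways with at least 2
query hits (resolving the ambiguous "more than 2" phrasing as k ≥ 2,
consistent with how two-member pathways are reported in practice), and
Bonferroni-adjusts across the *tested* pathways only. The background
universe defaults to the library universe rather than the 20 assayed
metabolites; both options exist because the original background is unstated.
The bundled KEGG-style and SMPDB-style mini-libraries are curated static
subsets at the granularity of common urinary metabolites; the interaction
network is a synthetic stand-in (clearly labelled in its filename) for a
chemical-interaction database extract, since live queries are out of scope.
Degree filtering keeps nodes with degree strictly greater than the cutoff
(default 2), always retaining the query metabolites.

## The synthetic-data generator

`generate_cohort()` draws log-normal concentrations: per-metabolite control
log-means spanning the orders of magnitude of urinary profiles, case shifts
applied on the log scale, and correlations induced by shared Gaussian latent
factors whose loadings (the Cholesky factor of the target correlation
matrix) hit the requested pairwise correlations exactly in expectation.
Defaults are the study conditions the analysis assumes: 50 controls vs 50
cases, 20 metabolites, planted shifts of +1.2 (guanidinoacetate), +1.0
(phenylacetylglycine), +0.8 (glycine), −0.9 (L-lactate) and −1.0
(L-alanine) in units of the log-scale standard deviation (all at or above
0.8 sd, graded like the observed importance ordering), correlation targets
0.93/0.67/0.64/0.65 for the four marker pairs, and 2% missingness injected
completely at random (no missingness mechanism is documented for the
reference cohort, so MCAR is the neutral choice). Monte-Carlo tests at
n = 5000 per group verify that empirical effects and correlations converge
to the targets within ±0.05.

`generate_spectrum()` renders each multiplet as Lorentzian lines (the
natural line shape for solution NMR, and analytically integrable) with
binomial intensity ratios; couplings convert to ppm via the 600.13 MHz
proton frequency; unresolved multiplets become one broad line at four times
the linewidth. Each line is normalized so its integral over the simulated
axis equals its target area, making total spectral area exactly
`tsp_area + Σ concentration × proton count`. The default axis runs −0.3 to
9.8 ppm at 16384 points — extended below 0 so the TSP reference singlet is
on-grid — with optional broad water (4.70 ppm) and urea (5.80 ppm) humps so
the exclusion logic has something to exclude.

What the generator does **not** emulate: phase/baseline artifacts,
pH-dependent shift drift, peak overlap beyond what the fixed shift table
implies, 2-D experiments, and any structured missingness. Passing tests on
synthetic cohorts therefore demonstrate that the *statistical machinery* is
correct and that markers of the planted size are recoverable at the stated
cohort size; they do not certify performance on real spectra, where shift
variability and baseline handling dominate. One subtlety the generator
documents rather than hides: the pairwise correlations are calibrated on
the *concentration* scale; after imputation of the injected zeros, the
processed-scale correlations at n = 100 can be noticeably attenuated, since
each imputed zero becomes a low outlier on the log scale.

## Problem sizes

The shipped tests run the full pipeline on 100 × 20 cohorts, Monte-Carlo
calibration at 5000 per group, permutation calibration over 50 replicates of
100 permutations each, and marker-recovery over 20 seeded cohorts — sizes
chosen so the whole suite stays comfortably within a few minutes on one CPU
while keeping every binomial bound sharp enough to be meaningful.

## Known limitations

- Two classes only; no multi-class PLS-DA, kernels, or automatic component
  selection beyond the quality-gate flags.
- Resubstitution ROC overstates real-world accuracy by construction; it is
  the faithful default here, not a recommendation.
- The enrichment libraries are deliberately small; p-values depend strongly
  on the chosen universe and should be read comparatively, not absolutely.
- JCAMP-DX support covers the evenly spaced `(X++(Y..Y))` form used for
  processed 1-D spectra, not compressed (DIF/DUP) encodings.
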