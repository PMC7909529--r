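# nmrbiomark

Biomarker discovery from one-dimensional ¹H-NMR urine metabolomics, built
for two-group (case vs control) cohort studies such as prostate-cancer
screening. The package covers the full path from spectra to candidate
markers: spectral referencing and binning, metabolite quantification against
the TSP internal standard, imputation/normalization/variance-stabilization,
supervised latent-variable modelling with permutation validation, univariate
screening, consensus marker selection, ROC panel evaluation and
hypergeometric pathway enrichment. A synthetic-data module simulates
realistic cohorts and spectra so every stage is testable without any
external download.

## The models at the core

**PCA / PLS-DA (NIPALS).** With `X` the column-scaled feature matrix and `y`
a centered 0/1 class label, each PLS component is

    w = Xᵀy / ‖Xᵀy‖,  t = Xw,  p = Xᵀt / tᵀt,  q = yᵀt / tᵀt,

followed by deflation `X ← X − t pᵀ`, `y ← y − t q`. Fit statistics are
R²X (fraction of X sum of squares per component), R²Y = 1 − ‖y − ŷ‖²/‖y‖²,
and Q² = 1 − PRESS/SSY from stratified 7-fold cross-validation.

**OPLS-DA (orthogonal signal correction).** Each orthogonal round removes the
X-variation uncorrelated with class: `w_orth = p − (wᵀp)w` (normalized),
`t_orth = X w_orth`, `X ← X − t_orth p_orthᵀ`; one predictive PLS component
is then fitted on the filtered matrix. Predictive and orthogonal scores are
exactly orthogonal, and OPLS-DA(1+h) explains y exactly as PLS-DA(1+h
components) does.

**VIP.** Variable importance in projection over the predictive components,

    VIPⱼ = √( p · Σₐ SSYₐ (w_ja/‖wₐ‖)² / Σₐ SSYₐ ),  SSYₐ = qₐ² tₐᵀtₐ,

normalized so mean(VIP²) = 1; `VIP > 1` marks influential features.

**Validation.** Class labels are permuted (default 100 times), the model and
Q² recomputed each time, and p-values follow the add-one rule
`p = (1 + #{permuted ≥ observed}) / (1 + n_perm)` — with 100 permutations
the smallest attainable p is 1/101 ≈ 0.0099.

**Consensus selection.** A metabolite is *prominent* when (i) at least two
of PCA (top-7 first-component contribution), PLS-DA and OPLS-DA (|normalized
loading| > 0.2) recommend it, (ii) its Bonferroni-adjusted Wilcoxon p is
below 0.01, and (iii) its OPLS-DA VIP exceeds 1.

## Worked example

```r
library(nmrbiomark)
report <- run_pipeline(pipeline_config(seed = 7))
print(report)
```

```
nmrbiomark pipeline report
  cohort: 100 samples x 20 features (seed 7)
  PCA R2X = 0.255 | PLS-DA R2Y = 0.504, Q2 = 0.308 | OPLS-DA R2Y = 0.504, Q2 = 0.308
  permutation p (Q2): PLS-DA 0.0099, OPLS-DA 0.0099
  prominent metabolites: L-lactate, L-alanine, guanidinoacetate, glycine, phenylacetylglycine
  panel (guanidinoacetate + phenylacetylglycine + L-alanine): AUC = 0.853, sens = 90%, spec = 76%
  quality gates not met: pca_r2x_gt_0.4, plsda_q2_gt_0.5, oplsda_q2_gt_0.5
```

The simulated 50 + 50 cohort plants five marker shifts (guanidinoacetate,
phenylacetylglycine and glycine up; L-lactate and L-alanine down). The run
above recovers all five as prominent with no false positive; both permutation
p-values sit at the 1/101 floor, i.e. no permuted model matched the observed
Q². PLS-DA(2) and OPLS-DA(1+1) report identical R²Y/Q² — that equality is an
algebraic property of orthogonal signal correction, not a coincidence. The
quality-gate flags record that this 20-feature synthetic table is noisier
than a real binned spectrum; they are advisory, never fatal.
`print(report$consensus)` breaks the selection into its three criterion
sets, and `write_pipeline_report(report, "out/")` serializes everything.

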