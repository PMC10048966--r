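---
title: "Modelling depression risk from SF-12 surveys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling depression risk from SF-12 surveys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sf12risk)
```

`sf12risk` models the risk of depression in patients recovering from cardiac
surgery, starting from the SF-12v2 quality-of-life questionnaire. This
vignette is the package's own account of the science: the models and their
assumptions, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
choices made where the underlying methods were described only conceptually.

## 1. SF-12 scoring and the risk label

The SF-12v2 has 12 items on 3- or 5-level response scales, grouped into eight
domains: physical functioning (PF), role-physical (RP), bodily pain (BP),
general health (GH), vitality (VT), social functioning (SF), role-emotional
(RE), and mental health (MH). Scoring proceeds in three steps:

1. **Item recoding.** Each item is linearly rescaled to 0–100 with 100 the
   best health state; items whose raw codes run opposite to health (e.g.
   general health, where 1 = "excellent") are reversed first. A domain score
   is the mean of its items, so it is bounded in [0, 100] and monotone in
   every single-item improvement — both properties are tested exhaustively
   over the (small) per-domain response spaces.
2. **Norm-based component summaries.** Each domain is z-standardized against
   a normalization mean/SD, the z-scores are combined with physical (PCS) and
   mental (MCS) weight vectors, and the sums are T-transformed:
   `T = 50 + 10 · Σⱼ wⱼ zⱼ`. The engine is deliberately *manual-agnostic*:
   the constants live in a `ScoringCoefficients` table (CSV-pluggable,
   schema `domain, norm_mean, norm_sd, pcs_weight, mcs_weight`), because the
   instrument's licensed manual constants cannot be redistributed. The
   shipped default table is synthetic; see §5 for how it was fixed.
3. **Screening rule.** `depression_risk = 1` iff `MCS < 42`, read strictly:
   a patient at exactly 42.00 is *not* flagged. The flag is therefore a
   non-increasing step function of MCS (tested as a property).

**Missing items.** Records with missing items are rejected by default. An
optional half-scale policy scores a domain as the mean of its answered items
when at least half were answered — the classical half-scale rule — and is off
by default because the motivating study reports no missing-data handling.

**Rounding.** Prevalence is displayed as `count / n × 100` to two decimals
(63/217 → 29.03%); all internal values keep full precision, and the exact
identity `prevalence × n = count` is tested.

## 2. The synthetic cohort: a stated world

The study's patient-level data are available only on request, so every
downstream stage is exercised on synthetic cohorts from a generative model
whose structure is the smallest one that supports the published qualitative
findings:

- Each patient has latent **mental** and **physical** health factors, a
  correlated bivariate normal (default correlation ρ = 0.3, unit variances).
- The eight domains load on the two factors in a block pattern (mental block:
  VT .95, RE .72, MH .62, SF .55; physical block: PF .85, RP .80, BP .60,
  GH .60, with small cross-loadings), plus residual noise chosen so every
  domain's latent score has unit variance before rescaling to its published
  mean/SD (e.g. VT 50.92 ± 25.78).
- Items are nearest-level quantizations of the domain latent plus item noise
  (SD 5 points on the 0–100 scale), clamped to the instrument's range and
  re-oriented for reverse-coded items.
- Binary clinical covariates come from logistic links on the latent factors
  with intercepts solved (by 1-D Gaussian quadrature) to match the published
  marginals exactly: heart failure 27.2% (slopes −0.9 physical, −0.3
  mental), NYHA II–IV 71.9% (−1.1, −0.4), CCS II–IV 79.7% (−0.8 physical),
  male 65.4% (no link). Age is N(65.14, 9.47²); EUROscore is lognormal
  matched to the published mean/median with a mild negative physical link.
- **The label is not simulated.** Generated items are pushed through the real
  scoring pipeline, so the generator and the scorer share a single
  definition of risk.

**Calibration.** `calibrate_prevalence()` adjusts the mental-factor location
by bisection until the large-n simulated prevalence of `MCS < 42` is within
`tol` (default 0.005, internally refined toward `tol/2`) of the target
0.2903. Each bisection step simulates one 50,000-patient cohort under a
fixed evaluation seed, making the objective deterministic and monotone.

**Reproducibility.** One root seed fans out to named child streams (latents,
domain noise, items, covariates; and in the pipeline: calibration, cohort,
GPCA, benchmark), so cohorts are bit-for-bit reproducible and stages are
independently replayable.

### What the generator does *not* emulate

The generator reproduces marginals and one plausible dependence structure;
it does not fit the real data (unavailable), does not model covariate–
covariate dependence beyond what the shared latent factors induce (e.g. the
real HF × NYHA overlap is unknown), and makes the label a *deterministic*
function of the item responses. That last point matters when reading test
output: cross-validated classifier accuracies on synthetic cohorts run far
above the published real-data grid (≈ 0.97 vs ≈ 0.82), because nothing
separates the label from the features except quantization noise. A green
benchmark test therefore establishes the harness (no leakage, calibration at
chance under permuted labels, determinism) — not that the published accuracy
is reproduced. The published model metrics (82.53% variance explained, the
0.819 accuracy cell, the published node risks) are never asserted.

## 3. The five reducers

All five estimators standardize features internally (constant columns are
dropped with a warning), share one contract — `fit(X[, labels], k)` →
orthonormal axes, per-axis variances, loadings, variance-explained fractions
— and define **loadings uniformly as Pearson correlations between original
features and component scores**, so the |λ| > 0.7 assignment rule is
method-agnostic. Axes are sign-oriented so each axis's largest-|loading|
feature loads positively.

- **PCA**: eigendecomposition of the sample covariance of standardized
  features; tested to < 10⁻⁴ degrees against an independent dense eigen
  oracle.
- **KPCA**: double-centered kernel eigendecomposition; RBF kernel with
  median-heuristic bandwidth by default (both configurable). Variance
  explained is the kernel-eigenvalue fraction; with the linear kernel it
  equals PCA's to 10⁻⁸. Feature-space axes have no pre-image for nonlinear
  kernels, so the model stores sample coefficients and supports out-of-sample
  projection by centered cross-kernel. Small negative eigenvalues after
  centering are clamped; larger ones trigger a jitter-and-retry repair.
- **GPCA** (gradient/Hebbian PCA): components extracted one at a time by
  Oja-rule updates with deflation. A purely per-sample stochastic pass with
  learning rate `eta0/(t + t0)` orbits the optimum inside a step-size noise
  ball (we measured ~20° residual error), so each component runs the
  stochastic phase (100 shuffled epochs) and is then *polished* by the same
  Hebbian update driven by the sample covariance — deterministic gradient
  ascent on projected variance — until the direction drift falls below
  10⁻⁹. Non-convergence is flagged in the model's diagnostics. GPCA agrees
  with the eigen oracle to < 2° across 20 random 50×6 matrices (tested).
- **CCPCA** (centroid-class PCA): the source describes the method only
  conceptually ("rotation of the normalized feature space according to the
  classes' centroids"). The package's **reconstruction**: (1) standardize;
  (2) orthonormalize the span of class-centroid offsets from the grand mean
  — for K classes at most K−1 "class-oriented" leading axes, ordered by
  projected variance; (3) ordinary PCA in the orthogonal complement;
  (4) variance accounting against total feature variance. A single class (or
  coincident centroids) falls back to plain PCA with a warning, and the
  degeneracy is tested. This is flagged as a reconstruction, not a certified
  reimplementation of the cited method.
- **LDA hybrid**: binary LDA has a single discriminant, so "variance
  explained by k components" is ill-posed; mirroring the CCPCA construction,
  axis 1 is the Fisher direction (within-class-scatter-whitened centroid
  difference, ridge-regularized with the ridge logged when Sw is near
  singular) and axes 2..k are complement PCA. The Fisher axis matches the
  closed-form two-class solution to numerical precision (tested).

**Discriminant-power ranking** scores each feature as
`Σ over retained components |loading| × variance-explained fraction`;
class-oriented components occupy the model's leading positions, so any
retention cutoff keeps them first ("class-oriented components weighted
first" is read as this ordering guarantee). Ties break by feature name.

**Feature assignment** is strict: a feature joins the component where its
|loading| is maximal, and only if that |loading| > 0.7 (exactly 0.7 is
excluded); each feature is claimed by at most one component. When the rule
selects fewer than two features on a given run, the pipeline falls back to
the top-4 discriminant-ranked features and records the fallback in the run
manifest.

## 4. Benchmark and risk tree

**Benchmark.** The published experiment's validation scheme is not stated;
the package uses stratified 5-fold cross-validation with 10 repeats (3 in
the pipeline default, 2 in the acceptance script, chosen to keep runtimes in
budget — the scheme is always recorded in the grid's metadata). Within every
fold, standardization and the supervised reducer are fitted on the training
split only; the "NO" column uses the standardized raw features. Classifier
defaults (all recorded in `bench_config`): unpenalized logistic regression
(the "Regg" row, masked to the NO column to mirror the published table
shape), k-NN with k = 5 (FNN), soft-margin RBF-SVM with C = 1 and
γ = 1/p solved in the dual with `quadprog`, a one-hidden-layer tanh MLP (16
units, 1000 full-batch iterations with momentum, seeded init), in-package
CART (Gini, min-leaf 5% of n), and Gaussian naive Bayes. `select_best()`
takes the accuracy argmax; ties prefer fewer components (the unreduced NO
column ranks last) then roster order. rpart/e1071/nnet are deliberately not
dependencies: CART is also the final model of the analysis and is authored
in-package; SVM/MLP/GNB are small self-contained implementations against the
same contract.

**Risk tree.** CART here is a *risk* tree: recursive binary Gini
partitioning (depth ≤ 3 by default, min-leaf 5% of n, thresholds at
midpoints of consecutive distinct values, deterministic tie-breaks by
impurity gain, then column order, then smaller threshold) over the raw
selected features — raw, not component scores, because the published tree's
thresholds live on raw scales. Every node carries `n`, the class-1 count,
the risk `n1/n` (a-priori at the root, a-posteriori below) and the signed
delta against its parent. Two exact invariants are enforced and tested:
count conservation (`n` and `n1` sum across children; `risk·n` is an integer
count) and child-risk bracketing (min child ≤ parent ≤ max child, a property
of proportions). Binary covariates are encoded 1 = NYHA III–IV, 1 = heart
failure present. The NYHA dichotomization point is ambiguous in the source
(0–I vs II–IV in the cohort table, "class I or II = 0" in the narrative);
the generator's covariate is defined by its marginal (71.9% high), and the
encoding is configuration.

## 5. Numerical and design choices

- **Default scoring coefficients.** Two spec-level targets interact: the
  calibrated generator must hit prevalence 0.2903 *and* keep domain means at
  their published values (e.g. VT 50.92 ± 5 at n = 217 averaged over
  seeds). Since the calibration shifts the mental-factor location — and with
  it every mental domain mean — the synthetic norm means were chosen so that
  published-level domain scores already imply ≈ 29% prevalence, leaving the
  calibration shift near zero (fitted: ≈ +0.08 SD). Likewise the MCS weight
  vector puts its largest weight on VT (.45) and second on RE (.36),
  matching the driver hierarchy the generator is specified to emulate
  (vitality first, role-emotional second); with RE-heavy weights the risk
  tree recovers RE first, contradicting the target world. Both choices were
  fixed before the test expectations were frozen, and both are plain
  configuration: real studies should load the licensed coefficient table.
- **Degenerate inputs**: all-constant feature matrices, single-class labels,
  non-bracketable calibration targets, out-of-range `k`, classes smaller
  than the fold count, and non-finite MCS all raise typed errors
  (`sf12risk_config_error`, `sf12risk_validation_error`,
  `sf12risk_calibration_error`, `sf12risk_stratification_error`); grid cells
  whose classifier fails are marked failed with the diagnostic rather than
  aborting the run.
- **Tolerances**: axis orthonormality 10⁻⁸; variance conservation 10⁻¹⁰;
  GPCA drift 10⁻⁹ (≈ 0.08° directional resolution); KPCA PSD tolerance
  10⁻⁸ relative; centroid-coincidence tolerance 10⁻⁸.
- **Tie-breaks**: split candidates by gain, then column order, then smaller
  threshold; feature assignment by first (leading) component on exact
  |loading| ties; `select_best` by fewer components then roster order;
  ranking ties by feature name.
- **What stays red by design**: nothing in the shipped suite — but the
  published real-data numbers (82.53%, 0.819, the figure's node risks) are
  not targets at all, because the data behind them are not deposited. The
  acceptance-target list is accordingly empty and `scripts/acceptance.R`
  writes `{}` after an end-to-end integrity run.

## 6. Known limitations

- CCPCA and GPCA are reconstructions from conceptual descriptions; fidelity
  to the originally cited algorithms cannot be verified from the available
  text. The run manifest carries this warning on every pipeline run.
- The shipped coefficient table is synthetic. MCS/PCS values produced with it
  are internally consistent but not comparable to scores from the licensed
  manual, and no country-specific norm set is included.
- The generator's covariate dependence is declared, not inferred; only the
  marginals are anchored to published values.
- The benchmark does no hyperparameter search, and accuracy is the only
  surfaced metric (mirroring the published table); the fold-level detail
  array is retained for anything further.
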