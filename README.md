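# sf12risk

Depression-risk modelling from SF-12v2 health surveys in post-cardiac-surgery
cohorts.

About one in three patients screens positive for depression risk in the months
after cardiac surgery, and the screening instrument is often the SF-12v2: its
mental component summary (MCS), a norm-based T-score (population mean 50,
SD 10), flags risk when **MCS < 42**. `sf12risk` re-implements, as a tested and
reusable R pipeline, the analysis used to model that risk:

1. **SF-12 scoring** — 12 item responses → 8 domain scores on 0–100 (PF, RP,
   BP, GH, VT, SF, RE, MH) → norm-based PCS/MCS T-scores
   (`T = 50 + 10 · Σⱼ wⱼ zⱼ`, with a pluggable coefficient table) → binary
   depression-risk label.
2. **Five dimensionality reducers** under one estimator contract: classical
   PCA, kernel PCA (RBF, median-heuristic bandwidth), gradient/Hebbian PCA
   (Oja-rule stochastic ascent plus deterministic polishing), centroid-class
   PCA (class-centroid span first, complement PCA after), and a Fisher-LDA /
   PCA hybrid — compared by cumulative % variance explained, with
   discriminant-power feature ranking and strict |λ| > 0.7 loading-based
   feature assignment.
3. **Classifier benchmark** — logistic regression, k-NN, RBF-SVM, MLP, CART
   and Gaussian naive Bayes on raw features ("NO") and on 1–6 retained
   supervised components, under repeated stratified cross-validation with
   reducers refitted inside each training fold.
4. **CART risk tree** — recursive Gini partitioning of the selected raw
   features, reporting the a-priori risk at the root and a-posteriori risks
   and signed risk deltas at every node, with text/DOT/JSON renderings and an
   exact count-conservation check.
5. **Synthetic-cohort generator** — the study data are not deposited, so a
   seeded two-latent-factor generator emulates the published cohort (n = 217,
   prevalence 29.03%, Table-level domain means/SDs and covariate marginals)
   and is calibrated to the target prevalence by bisection on the
   mental-factor location.

## Worked example

```r
library(sf12risk)

cfg  <- calibrate_prevalence(synthetic_config())   # target 29.03% risk
co   <- generate_cohort(cfg, seed = 3)
summarize_cohort(co)$prevalence_pct
#> [1] 29.49

feats <- cohort_features(co)
cmp   <- compare_reducers(feats$X, feats$labels, k = 4)
cmp$table
#>   method pct_variance_explained
#> 1    PCA                  56.30
#> 2   KPCA                  42.51
#> 3   GPCA                  56.30
#> 4  CCPCA                  56.12
#> 5    LDA                  55.23

tree <- fit_risk_tree(co, co$depression_risk,
                      tree_config(features = c("VT", "RE", "nyha_high",
                                               "heart_failure")))
print(tree)
#> a-priori risk | n=217 | risk=29.49%
#>   VT < 37.5 | n=71 | risk=77.46% (+47.97%)
#>     RE < 68.75 | n=55 | risk=87.27% (+9.81%)
#>       RE < 43.75 | n=21 | risk=100.00% (+12.73%)
#>       RE >= 43.75 | n=34 | risk=79.41% (-7.86%)
#>     RE >= 68.75 | n=16 | risk=43.75% (-33.71%)
#>   VT >= 37.5 | n=146 | risk=6.16% (-23.33%)
#>     RE < 56.25 | n=38 | risk=23.68% (+17.52%)
#>     RE >= 56.25 | n=108 | risk=0.00% (-6.16%)
```

(Output from seed 3; your numbers match exactly at the same seed.) Read the
tree as a clinical risk figure: 29.49% a-priori risk; vitality below 37.5
points raises it to 77.46% a-posteriori; low role-emotional raises it
further — each node shows `n`, risk %, and the signed change against its
parent. Accuracies from
`run_grid()` on synthetic cohorts run far above the published real-data grid
(≈ 0.8): the synthetic label is a deterministic function of the domain
scores, which an 8-domain classifier can almost recover. See the methods
vignette for what green tests do and do not establish.

The full pipeline with all artifacts (scored cohort, variance and eigenvalue
tables, accuracy grid, ranking, tree JSON/DOT, manifest):

```r
run <- run_pipeline(pipeline_config(out_dir = "run1", seed = 7))
cat(make_report(run), sep = "\n")
```

or from the shell via `inst/cli/sf12risk`:

```sh
Rscript inst/cli/sf12risk run-all --out run1 --seed 7
```

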