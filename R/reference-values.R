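#' Published reference targets the synthetic generator emulates
#'
#' Cohort statistics printed for the motivating post-cardiac-surgery study
#' (n = 217): depression-risk prevalence, SF-12 domain and component means/SDs,
#' and clinical covariate marginals. These are *emulation targets* for the
#' synthetic-cohort generator and labels for comparison reports — they are
#' configuration, not ground truth, and the package never asserts that a
#' synthetic run reproduces the study's real-data model metrics.
#'
#' @return nested list: `n`, `prevalence`, `domains` (mean/sd per domain),
#'   `components` (PCS/MCS mean/sd), `covariates` (marginal rates and
#'   distribution parameters).
#' @export
reference_targets <- function() {
  list(
    n = 217L,
    prevalence = 0.2903,
    risk_count = 63L,
    domains = data.frame(
      domain = sf12_domains(),
      mean = c(49.54, 48.67, 60.48, 47.86, 50.92, 64.19, 65.44, 64.98),
      sd   = c(30.80, 22.60, 27.15, 19.92, 25.78, 26.95, 26.39, 20.74),
      stringsAsFactors = FALSE
    ),
    components = data.frame(
      component = c("PCS", "MCS"),
      mean = c(40.94, 47.87),
      sd   = c(7.86, 10.0),
      stringsAsFactors = FALSE
    ),
    covariates = list(
      male = 0.654,
      heart_failure = 0.272,
      nyha_high = 0.719,   # NYHA II-IV vs 0-I
      ccs_high = 0.797,    # CCS II-IV vs 0-I
      age_mean = 65.14, age_sd = 9.47,
      euroscore_median = 1.49, euroscore_mean = 1.86,
      surgery = c(cabg = 0.567, single_non_cabg = 0.203, combined = 0.230)
    )
  )
}
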