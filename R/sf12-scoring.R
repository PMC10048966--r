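#' SF-12v2 item map
#'
#' Metadata describing the 12 SF-12v2 items: the domain each belongs to, the
#' number of response levels (3- or 5-level scales), and whether the raw code
#' runs opposite to health (reverse-scored items, where code 1 is the *best*
#' health state). Domains: physical functioning (PF, items 2-3), role-physical
#' (RP, 4-5), bodily pain (BP, 8), general health (GH, 1), vitality (VT, 10),
#' social functioning (SF, 12), role-emotional (RE, 6-7), mental health
#' (MH, 9 and 11).
#'
#' The scoring engine is generic over this table, so toy instruments (e.g. a
#' 3-item domain used in imputation tests) can reuse the same machinery.
#'
#' @return data.frame with columns `item`, `domain`, `levels`, `reverse`.
#' @export
sf12_item_map <- function() {
  data.frame(
    item    = paste0("sf12_q", 1:12),
    domain  = c("GH", "PF", "PF", "RP", "RP", "RE", "RE", "BP", "MH", "VT", "MH", "SF"),
    levels  = c(5L, 3L, 3L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L),
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Canonical SF-12 domain order
#' @return character vector of the eight domain abbreviations.
#' @export
sf12_domains <- function() c("PF", "RP", "BP", "GH", "VT", "SF", "RE", "MH")

#' Validate raw SF-12 item responses
#'
#' Checks that every item column is present, integer-coded, and within its
#' declared response range. Missing values are rejected unless the half-scale
#' imputation policy is enabled, in which case they are allowed through for
#' [score_domains()] to impute (an item is imputable only when at least half
#' of its domain's items were answered).
#'
#' @param raw data.frame with one row per respondent and the item columns of
#'   `item_map` (default `sf12_q1` .. `sf12_q12`).
#' @param item_map item metadata table, see [sf12_item_map()].
#' @param impute missing-data policy: `"none"` (reject records with missing
#'   items, the default) or `"halfscale"`.
#' @return the item columns of `raw`, validated, with class `sf12_responses`
#'   and attributes `item_map` and `impute`.
#' @export
validate_responses <- function(raw, item_map = sf12_item_map(),
                               impute = c("none", "halfscale")) {
  impute <- match.arg(impute)
  if (is.null(dim(raw))) raw <- as.data.frame(as.list(raw))
  missing_cols <- setdiff(item_map$item, names(raw))
  if (length(missing_cols) > 0) {
    abort_sf12(sprintf("missing item column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               class = "sf12risk_validation_error")
  }
  resp <- raw[, item_map$item, drop = FALSE]
  for (i in seq_len(nrow(item_map))) {
    col <- item_map$item[i]
    x <- resp[[col]]
    if (all(is.na(x))) x <- as.numeric(x)   # all-NA columns parse as logical
    if (!is.numeric(x)) {
      abort_sf12(sprintf("item %s must be numeric response codes", col),
                 class = "sf12risk_validation_error")
    }
    resp[[col]] <- x
    bad_na <- is.na(x)
    if (any(bad_na) && impute == "none") {
      abort_sf12(sprintf("item %s has %d missing value(s); enable impute = \"halfscale\" or drop the record",
                         col, sum(bad_na)),
                 class = "sf12risk_validation_error")
    }
    ok <- is.na(x) | (x == round(x) & x >= 1 & x <= item_map$levels[i])
    if (!all(ok)) {
      abort_sf12(sprintf("item %s: response code out of allowed range 1..%d (first offender: %s)",
                         col, item_map$levels[i], format(x[!ok][1])),
                 class = "sf12risk_validation_error")
    }
  }
  structure(resp, class = c("sf12_responses", "data.frame"),
            item_map = item_map, impute = impute)
}

# recode one item column to the 0-100 health scale (100 = best health)
recode_item <- function(x, levels, reverse) {
  s <- (x - 1) / (levels - 1) * 100
  if (reverse) 100 - s else s
}

#' Score SF-12 responses into domain scores
#'
#' Each domain score is the mean of its (orientation-corrected) items linearly
#' rescaled to 0-100, with 100 the best possible health state. Under the
#' half-scale policy a respondent's domain score is the mean of the answered
#' items provided at least half of the domain's items were answered;
#' otherwise the record is rejected.
#'
#' @param resp an `sf12_responses` object from [validate_responses()].
#' @return data.frame of domain scores (one column per domain, in
#'   [sf12_domains()] order for the standard instrument).
#' @export
score_domains <- function(resp) {
  if (!inherits(resp, "sf12_responses")) {
    resp <- validate_responses(resp)
  }
  item_map <- attr(resp, "item_map")
  impute <- attr(resp, "impute")
  scored <- vapply(seq_len(nrow(item_map)), function(i) {
    recode_item(resp[[item_map$item[i]]], item_map$levels[i], item_map$reverse[i])
  }, numeric(nrow(resp)))
  scored <- matrix(scored, nrow = nrow(resp))
  domains <- unique(item_map$domain)
  std <- sf12_domains()
  if (setequal(domains, std)) domains <- std
  out <- matrix(NA_real_, nrow(resp), length(domains),
                dimnames = list(NULL, domains))
  for (d in domains) {
    idx <- which(item_map$domain == d)
    block <- scored[, idx, drop = FALSE]
    n_ans <- rowSums(!is.na(block))
    if (impute == "halfscale") {
      enough <- n_ans >= ceiling(length(idx) / 2)
      if (any(!enough)) {
        abort_sf12(sprintf("domain %s: fewer than half of its items answered for %d record(s); cannot impute",
                           d, sum(!enough)),
                   class = "sf12risk_validation_error")
      }
      out[, d] <- rowMeans(block, na.rm = TRUE)
    } else {
      out[, d] <- rowMeans(block)
    }
  }
  as.data.frame(out)
}

#' Default norm-based scoring coefficients
#'
#' The scoring engine is manual-agnostic: component summaries are computed
#' from a pluggable coefficient table (per-domain normalization means/SDs and
#' PCS/MCS factor-score weights). This default set is a *synthetic* stand-in
#' whose structure mirrors US general-population norm-based scoring (mental
#' domains weight positively on MCS, physical domains on PCS, with small
#' negative cross-weights); the licensed manual constants are not
#' redistributed. Among the mental domains, vitality carries the largest MCS
#' weight and role-emotional the second, mirroring the qualitative driver
#' ordering of the motivating cardiac-surgery cohort. Replace the table via
#' [read_scoring_coefficients()] for real studies.
#'
#' @return data.frame with columns `domain`, `norm_mean`, `norm_sd`,
#'   `pcs_weight`, `mcs_weight`; exactly 8 rows, class `scoring_coefficients`.
#' @export
default_scoring_coefficients <- function() {
  coef <- data.frame(
    domain     = sf12_domains(),
    norm_mean  = c(81.2, 80.5, 75.5, 70.1, 52.3, 82.0, 85.0, 70.0),
    norm_sd    = c(29.1, 34.0, 23.6, 21.0, 24.0, 22.9, 29.3, 18.1),
    pcs_weight = c(0.42, 0.35, 0.32, 0.25, 0.03, -0.01, -0.19, -0.22),
    mcs_weight = c(-0.10, -0.08, -0.06, -0.02, 0.45, 0.20, 0.36, 0.32),
    stringsAsFactors = FALSE
  )
  validate_scoring_coefficients(coef)
}

#' Validate a scoring-coefficient table
#' @param coef data.frame with the coefficient schema.
#' @return the table with class `scoring_coefficients`.
#' @export
validate_scoring_coefficients <- function(coef) {
  need <- c("domain", "norm_mean", "norm_sd", "pcs_weight", "mcs_weight")
  if (!all(need %in% names(coef))) {
    abort_sf12(sprintf("coefficient table must have columns %s",
                       paste(need, collapse = ", ")),
               class = "sf12risk_config_error")
  }
  if (nrow(coef) != 8L || !setequal(coef$domain, sf12_domains())) {
    abort_sf12("coefficient table must have exactly 8 rows, one per SF-12 domain",
               class = "sf12risk_config_error")
  }
  if (any(!is.finite(coef$norm_sd)) || any(coef$norm_sd <= 0)) {
    abort_sf12("norm_sd entries must be strictly positive",
               class = "sf12risk_config_error")
  }
  coef <- coef[match(sf12_domains(), coef$domain), ]
  rownames(coef) <- NULL
  class(coef) <- c("scoring_coefficients", "data.frame")
  coef
}

#' Read / write scoring coefficients as CSV
#' @param path CSV path with columns `domain, norm_mean, norm_sd, pcs_weight, mcs_weight`.
#' @return a validated `scoring_coefficients` table.
#' @export
read_scoring_coefficients <- function(path) {
  validate_scoring_coefficients(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_scoring_coefficients
#' @param coef a `scoring_coefficients` table.
#' @export
write_scoring_coefficients <- function(coef, path) {
  utils::write.csv(validate_scoring_coefficients(coef), path, row.names = FALSE)
  invisible(path)
}

#' Compute PCS and MCS component summaries
#'
#' Norm-based scoring: each domain score is z-standardized against the
#' coefficient table's normalization mean/SD, the z-scores are combined with
#' the PCS and MCS weight vectors, and the weighted sums are T-transformed
#' (x 10 + 50) so both summaries live on a population mean-50 / SD-10 metric.
#'
#' @param dom data.frame of the eight domain scores (columns named as
#'   [sf12_domains()]).
#' @param coef a `scoring_coefficients` table; default
#'   [default_scoring_coefficients()].
#' @return data.frame with columns `PCS`, `MCS`.
#' @export
score_components <- function(dom, coef = default_scoring_coefficients()) {
  coef <- validate_scoring_coefficients(coef)
  missing_d <- setdiff(sf12_domains(), names(dom))
  if (length(missing_d) > 0) {
    abort_sf12(sprintf("domain score column(s) missing: %s",
                       paste(missing_d, collapse = ", ")),
               class = "sf12risk_validation_error")
  }
  z <- sweep(sweep(as.matrix(dom[, sf12_domains(), drop = FALSE]),
                   2, coef$norm_mean, "-"),
             2, coef$norm_sd, "/")
  data.frame(PCS = 50 + 10 * drop(z %*% coef$pcs_weight),
             MCS = 50 + 10 * drop(z %*% coef$mcs_weight))
}

#' Flag depression risk from the mental component summary
#'
#' Screening rule: label 1 when MCS is strictly below 42 T-score points,
#' 0 otherwise (an MCS of exactly 42 is not at risk).
#'
#' @param comp data.frame with an `MCS` column, or a numeric MCS vector.
#' @param threshold screening cut-point, default 42.
#' @return integer vector of 0/1 labels.
#' @export
flag_depression_risk <- function(comp, threshold = 42) {
  mcs <- if (is.data.frame(comp)) comp$MCS else comp
  if (is.null(mcs)) abort_sf12("no MCS column found")
  if (any(!is.finite(mcs))) {
    abort_sf12("non-finite MCS value(s); cannot assign depression-risk label")
  }
  as.integer(mcs < threshold)
}

#' Score a cohort end-to-end
#'
#' Convenience wrapper: validate items, score domains, compute PCS/MCS, and
#' attach the depression-risk label. Clinical covariate columns in `cohort`
#' are passed through untouched.
#'
#' @param cohort data.frame with `sf12_q1..sf12_q12` plus any covariates.
#' @inheritParams score_components
#' @inheritParams validate_responses
#' @return `cohort` with appended columns `PF..MH`, `PCS`, `MCS`,
#'   `depression_risk`.
#' @export
score_cohort <- function(cohort, coef = default_scoring_coefficients(),
                         impute = "none") {
  resp <- validate_responses(cohort, impute = impute)
  dom <- score_domains(resp)
  comp <- score_components(dom, coef)
  out <- cbind(cohort[setdiff(names(cohort), names(dom))], dom, comp)
  out$depression_risk <- flag_depression_risk(comp)
  out
}

#' Summarize a scored cohort
#'
#' Per-domain mean and SD, PCS/MCS mean and SD, risk count and prevalence
#' (count / n x 100, reported to two decimals as in standard cohort tables;
#' the unrounded value is kept alongside).
#'
#' @param scored data.frame from [score_cohort()] (needs domain columns,
#'   `PCS`, `MCS`, `depression_risk`).
#' @return list with elements `table` (statistic data.frame), `n`,
#'   `risk_count`, `prevalence_pct` (two decimals), `prevalence` (exact).
#' @export
summarize_cohort <- function(scored) {
  if (nrow(scored) == 0L) abort_sf12("cannot summarize an empty cohort")
  vars <- c(sf12_domains(), "PCS", "MCS")
  missing_v <- setdiff(c(vars, "depression_risk"), names(scored))
  if (length(missing_v) > 0) {
    abort_sf12(sprintf("scored cohort lacks column(s): %s",
                       paste(missing_v, collapse = ", ")))
  }
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)  # single-patient SD reported as 0
  tab <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(scored[[v]]), 0),
    sd   = vapply(vars, function(v) sd0(scored[[v]]), 0),
    row.names = NULL
  )
  n <- nrow(scored)
  k <- sum(scored$depression_risk)
  list(table = tab, n = n, risk_count = k,
       prevalence = k / n,
       prevalence_pct = round(100 * k / n, 2))
}
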