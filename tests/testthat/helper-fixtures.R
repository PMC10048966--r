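# shared fixtures; everything is generated in code, no stored data

# calibrated default config is expensive (~4 s): compute once per test run
.fixture_env <- new.env(parent = emptyenv())

calibrated_cfg <- function() {
  if (is.null(.fixture_env$cal)) {
    .fixture_env$cal <- calibrate_prevalence(synthetic_config())
  }
  .fixture_env$cal
}

# a small valid response set: one row per requested patient, all items at the
# given code (clamped to each item's level count)
uniform_responses <- function(n = 1, code = 1) {
  imap <- sf12_item_map()
  out <- as.data.frame(lapply(seq_len(nrow(imap)), function(i) {
    rep(min(code, imap$levels[i]), n)
  }))
  names(out) <- imap$item
  out
}

# responses at the best-health code for every item (reverse items -> code 1)
best_health_responses <- function(n = 1) {
  imap <- sf12_item_map()
  out <- as.data.frame(lapply(seq_len(nrow(imap)), function(i) {
    rep(if (imap$reverse[i]) 1L else imap$levels[i], n)
  }))
  names(out) <- imap$item
  out
}

worst_health_responses <- function(n = 1) {
  imap <- sf12_item_map()
  out <- as.data.frame(lapply(seq_len(nrow(imap)), function(i) {
    rep(if (imap$reverse[i]) imap$levels[i] else 1L, n)
  }))
  names(out) <- imap$item
  out
}

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# minimal reducer_model stub for pure-arithmetic operations
stub_model <- function(ve, axis_variances = NULL, class_axes = 0L,
                       loadings = NULL) {
  structure(list(method = "PCA",
                 variance_explained = ve,
                 axis_variances = axis_variances %||% ve,
                 loadings = loadings,
                 feature_names = if (!is.null(loadings)) rownames(loadings),
                 class_axes = class_axes,
                 k = length(ve)),
            class = "reducer_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
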