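#' Configuration for the classifier benchmark grid
#'
#' Defaults mirror the published experiment shape: six classifiers
#' (logistic regression "regg", k-NN, RBF-SVM, MLP, CART, Gaussian naive
#' Bayes) evaluated on the raw feature space ("NO" column) and on 1-6
#' retained supervised components, under repeated stratified k-fold
#' cross-validation. The validation scheme and all hyperparameters are
#' recorded in the output so every grid is labelled with how it was made.
#'
#' `column_mask` reproduces the printed table shape where logistic
#' regression appears only in the NO column; set it to `NULL` to fill every
#' cell.
#'
#' @param classifiers roster subset of
#'   `c("regg","knn","svm","mlp","cart","gnb")`.
#' @param components component counts to evaluate (default 1:6).
#' @param folds,repeats stratified CV folds (>= 2) and repeats.
#' @param seed root seed for fold assignment and stochastic learners.
#' @param hyper hyperparameter list (see [fit_classifier] defaults: k-NN
#'   k = 5, SVM RBF C = 1, MLP 16 hidden units / 1000 iterations, CART Gini
#'   with 5 percent min-leaf, unpenalized logistic regression).
#' @param column_mask named list mapping classifier -> allowed columns.
#' @export
bench_config <- function(classifiers = c("regg", "knn", "svm", "mlp", "cart", "gnb"),
                         components = 1:6, folds = 5L, repeats = 10L,
                         seed = 1L, hyper = list(),
                         column_mask = list(regg = "NO")) {
  if (length(classifiers) == 0) abort_sf12("classifier roster is empty",
                                           class = "sf12risk_config_error")
  bad <- setdiff(classifiers, c("regg", "knn", "svm", "mlp", "cart", "gnb"))
  if (length(bad) > 0) abort_sf12(sprintf("unknown classifier(s): %s",
                                          paste(bad, collapse = ", ")),
                                  class = "sf12risk_config_error")
  if (folds < 2) abort_sf12("folds must be >= 2", class = "sf12risk_config_error")
  structure(list(classifiers = classifiers, components = as.integer(components),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), hyper = hyper,
                 column_mask = column_mask),
            class = "bench_config")
}

# stratified fold assignment: each class spread evenly across folds
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (c0 in unique(labels)) {
    idx <- which(labels == c0)
    if (length(idx) < folds) {
      abort_sf12(sprintf("class %s has fewer members (%d) than folds (%d)",
                         c0, length(idx), folds),
                 class = "sf12risk_stratification_error")
    }
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Run the classifier x component-count accuracy grid
#'
#' For each CV fold the feature standardization and the supervised reducer
#' are fitted on the training split only, both splits are transformed, and
#' each classifier is trained and scored on the held-out fold — so no
#' information leaks from test folds into reduction or classification. The
#' "NO" column skips reduction (standardized raw features). Cells are mean
#' accuracy over folds x repeats, with the fold-level SD kept alongside;
#' a failing classifier marks its cell failed with the diagnostic rather
#' than aborting the grid.
#'
#' @param X feature matrix or data.frame (numeric).
#' @param labels 0/1 outcome, both classes with at least `folds` members.
#' @param cfg a [bench_config()].
#' @param reducer supervised reducer fitted per fold: `"ccpca"` (default) or
#'   `"lda"`.
#' @return object of class `accuracy_grid`: `accuracy` matrix (classifiers x
#'   columns), `sd` matrix, `failed` (diagnostics), `detail` (fold-level
#'   accuracies), `cfg`, `reducer`.
#' @export
run_grid <- function(X, labels, cfg = bench_config(), reducer = c("ccpca", "lda")) {
  reducer <- match.arg(reducer)
  X <- as.matrix(X)
  if (!all(labels %in% c(0, 1))) abort_sf12("labels must be binary 0/1")
  cols <- c("NO", as.character(cfg$components))
  acc_cells <- array(NA_real_,
                     dim = c(length(cfg$classifiers), length(cols),
                             cfg$folds * cfg$repeats),
                     dimnames = list(cfg$classifiers, cols, NULL))
  failures <- list()
  kmax <- max(cfg$components)
  slot <- 0L
  for (rep_i in seq_len(cfg$repeats)) {
    fold_of <- with_seed(child_seed(cfg$seed, paste0("cv_rep_", rep_i)),
                         stratified_folds(labels, cfg$folds))
    for (fold in seq_len(cfg$folds)) {
      slot <- slot + 1L
      tr <- fold_of != fold
      Xtr_raw <- X[tr, , drop = FALSE]
      Xte_raw <- X[!tr, , drop = FALSE]
      ytr <- labels[tr]; yte <- labels[!tr]
      red <- fit_reducer(reducer, Xtr_raw, k = min(kmax, ncol(X), sum(tr) - 1),
                         labels = ytr)
      Ztr <- apply_standardization(red, Xtr_raw)
      Zte <- apply_standardization(red, Xte_raw)
      Str <- Ztr %*% red$axes
      Ste <- Zte %*% red$axes
      for (ri in seq_along(cfg$classifiers)) {
        clf <- cfg$classifiers[ri]
        allowed <- cfg$column_mask[[clf]] %||% cols
        for (col in intersect(cols, allowed)) {
          if (col == "NO") {
            A <- Ztr; B <- Zte
          } else {
            k <- as.integer(col)
            if (k > ncol(Str)) next
            A <- Str[, seq_len(k), drop = FALSE]
            B <- Ste[, seq_len(k), drop = FALSE]
          }
          res <- tryCatch({
            pred <- fit_classifier(clf, A, ytr, hyper = cfg$hyper,
                                   seed = child_seed(cfg$seed,
                                                     paste(clf, col, slot, sep = "_")))
            mean(pred(B) == yte)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[paste(clf, col, sep = "|")]] <- conditionMessage(res)
          } else {
            acc_cells[ri, col, slot] <- res
          }
        }
      }
    }
  }
  acc <- apply(acc_cells, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  sdm <- apply(acc_cells, c(1, 2), function(v) {
    if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)
  })
  # distinguish masked-out cells from genuinely failed ones
  masked <- matrix(FALSE, length(cfg$classifiers), length(cols),
                   dimnames = dimnames(acc))
  for (ri in seq_along(cfg$classifiers)) {
    allowed <- cfg$column_mask[[cfg$classifiers[ri]]] %||% cols
    masked[ri, match(setdiff(cols, allowed), cols)] <- TRUE
  }
  structure(list(accuracy = acc, sd = sdm, masked = masked,
                 failed = failures, detail = acc_cells,
                 cfg = cfg, reducer = reducer,
                 scheme = sprintf("stratified %d-fold CV x %d repeats",
                                  cfg$folds, cfg$repeats)),
            class = "accuracy_grid")
}

#' @export
print.accuracy_grid <- function(x, ...) {
  cat(sprintf("<accuracy_grid: %s on %s components>\n", x$scheme, x$reducer))
  print(round(x$accuracy, 3))
  if (length(x$failed) > 0) {
    cat("failed cells:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select the best (classifier, component count) cell
#'
#' Argmax of mean accuracy over all evaluable cells; ties break by fewer
#' components, then roster order. The "NO" column is the full unreduced
#' feature space, so it ranks last in the fewer-components tie-break.
#'
#' @param grid an `accuracy_grid`.
#' @return list `classifier`, `column` ("NO" or a count), `components`
#'   (NA for "NO"), `accuracy`, `rationale`.
#' @export
select_best <- function(grid) {
  acc <- grid$accuracy
  if (all(is.na(acc))) abort_sf12("no evaluable cells in the grid")
  cols <- colnames(acc)
  comp_of <- ifelse(cols == "NO", Inf, suppressWarnings(as.numeric(cols)))
  best <- NULL
  for (ci in order(comp_of)) {          # fewer components first
    for (ri in seq_len(nrow(acc))) {    # roster order
      v <- acc[ri, ci]
      if (is.na(v)) next
      if (is.null(best) || v > best$accuracy + 1e-12) {
        best <- list(classifier = rownames(acc)[ri], column = cols[ci],
                     components = if (is.finite(comp_of[ci])) as.integer(comp_of[ci]) else NA_integer_,
                     accuracy = v)
      }
    }
  }
  best$rationale <- sprintf(
    "max mean accuracy %.3f at (%s, %s) under %s; ties break by fewer components then roster order",
    best$accuracy, best$classifier, best$column, grid$scheme)
  best
}

#' Accuracy grid as a display table
#' @param grid an `accuracy_grid`.
#' @param digits rounding for display (default 3, like published tables).
#' @return data.frame, one row per classifier; masked cells are `"-"`.
#' @export
grid_table <- function(grid, digits = 3) {
  acc <- round(grid$accuracy, digits)
  out <- data.frame(classifier = rownames(acc), stringsAsFactors = FALSE)
  for (cn in colnames(acc)) {
    col <- ifelse(grid$masked[, cn], "-",
                  ifelse(is.na(acc[, cn]), "failed",
                         formatC(acc[, cn], format = "f", digits = digits)))
    out[[cn]] <- col
  }
  out
}
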