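#' Standardize a feature matrix
#'
#' Centers every column to mean 0 and scales to SD 1. Constant columns carry
#' no information for variance-based reducers and are dropped with a warning;
#' an all-constant matrix is an error.
#'
#' @param X numeric matrix or data.frame (rows = observations).
#' @return standardized matrix with attributes `center`, `scale`,
#'   `dropped` (names of removed constant columns).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort_sf12("feature matrix must be numeric")
  if (any(!is.finite(X))) abort_sf12("feature matrix contains non-finite entries")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  const <- sds < 1e-12
  if (all(const)) abort_sf12("all features are constant; nothing to standardize")
  dropped <- colnames(X)[const]
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, sds, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- sds
  attr(Z, "dropped") <- dropped
  Z
}

# internal: apply a fitted model's stored standardization to new data
apply_standardization <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- model$feature_names
  X <- X[, model$feature_names, drop = FALSE]
  sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
}

# internal: orient axes so each axis's largest-|loading| feature loads positive,
# and recompute loadings (feature-score correlations) under that orientation
orient_and_load <- function(Z, axes, class_axes = 0L) {
  scores <- Z %*% axes
  loadings <- suppressWarnings(stats::cor(Z, scores))
  for (j in seq_len(ncol(axes))) {
    lj <- loadings[, j]
    if (all(is.na(lj))) next
    top <- which.max(abs(lj))
    if (lj[top] < 0) {
      axes[, j] <- -axes[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  scores <- Z %*% axes
  list(axes = axes, scores = scores, loadings = loadings)
}

# internal: assemble the common reducer_model structure
build_reducer_model <- function(method, Z, axes, k, class_axes = 0L,
                                center, scale, extra = list()) {
  o <- orient_and_load(Z, axes)
  axis_var <- apply(o$scores, 2, stats::var)
  total_var <- sum(apply(Z, 2, stats::var))
  ve <- axis_var / total_var
  model <- c(list(
    method = method,
    axes = o$axes,
    loadings = o$loadings,
    axis_variances = as.numeric(axis_var),
    variance_explained = as.numeric(ve),
    cumulative_variance_explained = cumsum(as.numeric(ve)),
    total_variance = total_var,
    k = k,
    n = nrow(Z),
    feature_names = colnames(Z),
    class_axes = class_axes,  # how many leading axes are class-oriented
    center = center, scale = scale
  ), extra)
  class(model) <- "reducer_model"
  model
}

#' @export
print.reducer_model <- function(x, ...) {
  cat(sprintf("<reducer_model: %s, k = %d, n = %d, p = %d>\n",
              x$method, x$k, x$n, length(x$feature_names)))
  cat(sprintf("  variance explained: %s (cumulative %.2f%%)\n",
              paste(sprintf("%.3f", x$variance_explained), collapse = ", "),
              100 * sum(x$variance_explained)))
  if (x$class_axes > 0)
    cat(sprintf("  leading %d axis/axes are class-oriented\n", x$class_axes))
  invisible(x)
}

#' Project data onto a fitted reducer's components
#'
#' @param object a `reducer_model`.
#' @param newdata matrix/data.frame on the original (unstandardized) feature
#'   scale; defaults to the training scores where stored.
#' @param ... unused.
#' @return n x k score matrix.
#' @export
predict.reducer_model <- function(object, newdata, ...) {
  Z <- apply_standardization(object, newdata)
  if (object$method == "KPCA") return(kpca_transform(object, Z))
  Z %*% object$axes
}

#' Principal component analysis
#'
#' Classical PCA via eigendecomposition of the sample covariance of the
#' standardized features: axes are the top-k eigenvectors, axis variances the
#' eigenvalues, and variance-explained fractions the eigenvalues over the
#' total variance.
#'
#' @param X feature matrix (rows = observations); standardized internally.
#' @param k number of components, `1 <= k <= min(n - 1, p)`.
#' @return a `reducer_model`.
#' @export
fit_pca <- function(X, k) {
  Z <- standardize_features(X)
  p <- ncol(Z); n <- nrow(Z)
  if (k < 1 || k > min(n - 1, p)) {
    abort_sf12(sprintf("k must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  axes <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(axes) <- colnames(Z)
  build_reducer_model("PCA", Z, axes, k,
                      center = attr(Z, "center"), scale = attr(Z, "scale"))
}

# median-heuristic RBF bandwidth: median pairwise Euclidean distance
median_bandwidth <- function(Z) {
  d <- stats::dist(Z)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

rbf_kernel <- function(A, B, sigma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Kernel principal component analysis
#'
#' Eigendecomposition of the double-centered kernel matrix. Variance
#' explained is the kernel-eigenvalue fraction. Feature-space axes have no
#' pre-image for nonlinear kernels, so `axes` holds the (scaled) sample
#' coefficient vectors and `loadings` are Pearson correlations between the
#' original features and the component scores, making downstream
#' loading-threshold feature assignment uniform across methods.
#'
#' @inheritParams fit_pca
#' @param kernel `"rbf"` (default, median-heuristic bandwidth unless `sigma`
#'   given) or `"linear"` (recovers classical PCA's variance fractions).
#' @param sigma RBF bandwidth; `NULL` = median heuristic.
#' @param jitter diagonal jitter added if centering leaves eigenvalues below
#'   `-tol` (numerical PSD repair); small negatives are clamped to zero.
#' @return a `reducer_model` with `kernel_cfg` metadata.
#' @export
fit_kpca <- function(X, k, kernel = c("rbf", "linear"), sigma = NULL,
                     jitter = 1e-10) {
  kernel <- match.arg(kernel)
  Z <- standardize_features(X)
  n <- nrow(Z)
  if (k < 1 || k > n - 1) abort_sf12("k must be in 1..(n-1) for KPCA")
  if (kernel == "rbf" && is.null(sigma)) sigma <- median_bandwidth(Z)
  K <- if (kernel == "linear") Z %*% t(Z) else rbf_kernel(Z, Z, sigma)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  Kc <- (Kc + t(Kc)) / 2
  eg <- eigen(Kc, symmetric = TRUE)
  vals <- eg$values
  tol <- 1e-8 * max(abs(vals), 1)
  if (min(vals) < -tol) {
    Kc <- Kc + diag(abs(min(vals)) + jitter, n)
    eg <- eigen(Kc, symmetric = TRUE)
    vals <- eg$values - (abs(min(vals)) + jitter)
  }
  vals <- pmax(vals, 0)
  lam <- vals[seq_len(k)]
  if (any(lam <= 0)) abort_sf12("kernel matrix rank too low for requested k")
  alpha <- eg$vectors[, seq_len(k), drop = FALSE]
  # scores = sqrt(lambda) * eigvec (unit-norm feature-space components)
  scores <- sweep(alpha, 2, sqrt(lam), "*")
  loadings <- suppressWarnings(stats::cor(Z, scores))
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (is.finite(loadings[top, j]) && loadings[top, j] < 0) {
      alpha[, j] <- -alpha[, j]
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  ve <- lam / sum(vals)
  model <- list(
    method = "KPCA",
    axes = NULL,  # no feature-space pre-image for nonlinear kernels
    alpha = alpha, lambda = lam,
    loadings = loadings,
    axis_variances = lam / (n - 1),
    variance_explained = as.numeric(ve),
    cumulative_variance_explained = cumsum(as.numeric(ve)),
    total_variance = sum(vals) / (n - 1),
    k = k, n = n,
    feature_names = colnames(Z),
    class_axes = 0L,
    center = attr(Z, "center"), scale = attr(Z, "scale"),
    kernel_cfg = list(kernel = kernel, sigma = sigma),
    train_Z = Z, train_K_colmeans = colMeans(K), train_K_mean = mean(K)
  )
  class(model) <- "reducer_model"
  model
}

# project new (already standardized) rows onto kernel components
kpca_transform <- function(model, Znew) {
  cfg <- model$kernel_cfg
  Kx <- if (cfg$kernel == "linear") Znew %*% t(model$train_Z)
        else rbf_kernel(Znew, model$train_Z, cfg$sigma)
  # double-center against the training kernel
  Kxc <- sweep(Kx, 2, model$train_K_colmeans, "-") -
    rowMeans(Kx) + model$train_K_mean
  Kxc %*% sweep(model$alpha, 2, sqrt(model$lambda), "/")
}

#' Gradient (Hebbian) principal component analysis
#'
#' Estimates PCA components by gradient ascent on the projected variance
#' with Oja-type Hebbian updates, extracting components one at a time with
#' deflation. Each component runs a stochastic phase — per-sample Oja
#' updates over shuffled epochs with learning rate `eta0 / (t + t0)` on the
#' global update count `t` — followed by deterministic full-gradient
#' polishing (the same Hebbian update driven by the sample covariance) until
#' the axis direction drifts less than `tol` (as `1 - |cos angle|`) between
#' iterations. Per-sample SGD alone orbits the optimum in a step-size noise
#' ball; the polishing phase removes that floor so converged axes match the
#' eigendecomposition solution to high angular precision. Non-convergence is
#' flagged in the model's diagnostics, never silently ignored.
#'
#' @inheritParams fit_pca
#' @param eta0,t0 learning-rate schedule constants for the stochastic phase.
#' @param sgd_epochs epochs of per-sample updates before polishing.
#' @param max_iter iteration cap for the polishing phase.
#' @param tol drift tolerance on the axis direction.
#' @param seed RNG seed for initialization and sample shuffling.
#' @return a `reducer_model` with a `convergence` element (per-component
#'   polish iterations and converged flags).
#' @export
fit_gpca <- function(X, k, eta0 = 5, t0 = 50, sgd_epochs = 100L,
                     max_iter = 5000L, tol = 1e-9, seed = 42L) {
  Z <- standardize_features(X)
  p <- ncol(Z); n <- nrow(Z)
  if (k < 1 || k > min(n - 1, p)) {
    abort_sf12(sprintf("k must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  axes <- matrix(0, p, k, dimnames = list(colnames(Z), NULL))
  conv <- data.frame(component = seq_len(k), sgd_epochs = NA_integer_,
                     polish_iters = NA_integer_, converged = NA)
  D <- Z
  with_seed(seed, {
    t_global <- 0
    for (j in seq_len(k)) {
      w <- stats::rnorm(p)
      w <- w / sqrt(sum(w^2))
      for (ep in seq_len(sgd_epochs)) {
        for (i in sample.int(n)) {
          t_global <- t_global + 1
          eta <- eta0 / (t_global + t0)
          x <- D[i, ]
          y <- sum(x * w)
          w <- w + eta * y * (x - y * w)   # Oja update (self-normalizing)
          w <- w / sqrt(sum(w^2))
        }
      }
      # deterministic Hebbian polishing on the sample covariance
      Cd <- crossprod(D) / (n - 1)
      eta_det <- 1 / max(colSums(abs(Cd)))  # < 1/lambda_max: stable step
      converged <- FALSE
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        w_prev <- w
        g <- drop(Cd %*% w)
        w <- w + eta_det * (g - sum(w * g) * w)
        w <- w / sqrt(sum(w^2))
        if (1 - abs(sum(w * w_prev)) < tol) { converged <- TRUE; break }
      }
      conv$sgd_epochs[j] <- sgd_epochs
      conv$polish_iters[j] <- it
      conv$converged[j] <- converged
      axes[, j] <- w
      D <- D - (D %*% w) %*% t(w)          # deflate before the next component
    }
  })
  # re-orthonormalize against accumulated floating-point drift
  qr_a <- qr(axes)
  axes_on <- qr.Q(qr_a) %*% diag(sign(diag(qr.R(qr_a))), k, k)
  rownames(axes_on) <- colnames(Z)
  m <- build_reducer_model("GPCA", Z, axes_on, k,
                           center = attr(Z, "center"), scale = attr(Z, "scale"),
                           extra = list(convergence = conv,
                                        opt_cfg = list(eta0 = eta0, t0 = t0,
                                                       sgd_epochs = sgd_epochs,
                                                       max_iter = max_iter,
                                                       tol = tol, seed = seed)))
  if (!all(conv$converged)) {
    warning(sprintf("GPCA: component(s) %s did not converge within %d polish iterations",
                    paste(conv$component[!conv$converged], collapse = ", "),
                    max_iter))
  }
  m
}

#' Centroid-class principal component analysis
#'
#' Supervised PCA variant that rotates the standardized feature space
#' according to the class centroids: the leading "class-oriented" axes span
#' the offsets of the class centroids from the grand mean (orthonormalized,
#' ordered by projected variance), and the remaining axes are ordinary PCA
#' directions in the orthogonal complement of that span. With K classes there
#' are at most K - 1 class-oriented axes. Degenerate cases: a single class
#' (or coincident centroids) falls back to plain PCA with a warning.
#'
#' @inheritParams fit_pca
#' @param labels class labels, length `nrow(X)`; every class needs >= 2
#'   members.
#' @param centroid_tol centroid offsets with norm below this are treated as
#'   coincident.
#' @return a `reducer_model`; `class_axes` records how many leading axes are
#'   class-oriented.
#' @export
fit_ccpca <- function(X, labels, k, centroid_tol = 1e-8) {
  Z <- standardize_features(X)
  p <- ncol(Z); n <- nrow(Z)
  if (length(labels) != n) abort_sf12("labels must match nrow(X)")
  if (k < 1 || k > min(n - 1, p)) {
    abort_sf12(sprintf("k must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  cls <- sort(unique(labels))
  if (any(table(labels) < 2)) {
    abort_sf12("every class must have at least 2 members")
  }
  if (length(cls) < 2) {
    warning("single class: centroid-class PCA reduces to plain PCA")
    m <- fit_pca(X, k)
    m$method <- "CCPCA"
    return(m)
  }
  offsets <- t(vapply(cls, function(c0) colMeans(Z[labels == c0, , drop = FALSE]),
                      numeric(p)))   # grand mean of standardized Z is 0
  qr_o <- qr(t(offsets), tol = centroid_tol)
  r <- min(qr_o$rank, length(cls) - 1L)
  if (r == 0L) {
    warning("class centroids coincide: falling back to plain PCA")
    m <- fit_pca(X, k)
    m$method <- "CCPCA"
    return(m)
  }
  class_basis <- qr.Q(qr_o)[, seq_len(r), drop = FALSE]
  # order class axes by projected data variance
  pv <- apply(Z %*% class_basis, 2, stats::var)
  class_basis <- class_basis[, order(pv, decreasing = TRUE), drop = FALSE]
  n_class <- min(r, k)
  axes <- class_basis[, seq_len(n_class), drop = FALSE]
  if (k > n_class) {
    # PCA in the orthogonal complement of the class span
    Proj <- diag(p) - class_basis %*% t(class_basis)
    Zc <- Z %*% Proj
    eg <- eigen(stats::cov(Zc), symmetric = TRUE)
    comp_axes <- eg$vectors[, seq_len(k - n_class), drop = FALSE]
    # project exactly into the complement and re-orthonormalize
    comp_axes <- Proj %*% comp_axes
    comp_axes <- qr.Q(qr(comp_axes))[, seq_len(k - n_class), drop = FALSE]
    axes <- cbind(axes, comp_axes)
  }
  rownames(axes) <- colnames(Z)
  build_reducer_model("CCPCA", Z, axes, k, class_axes = as.integer(n_class),
                      center = attr(Z, "center"), scale = attr(Z, "scale"),
                      extra = list(classes = cls,
                                   note = "centroid-span reconstruction; leading axes are class-oriented"))
}

#' Fisher-discriminant / PCA hybrid
#'
#' Axis 1 is the two-class Fisher discriminant direction (within-class
#' scatter-whitened centroid difference); axes 2..k are PCA directions in its
#' orthogonal complement, mirroring the centroid-class construction so that
#' "variance explained for k components" is well defined even though binary
#' LDA has a single discriminant.
#'
#' @inheritParams fit_ccpca
#' @param ridge ridge added to the within-class scatter when (near) singular;
#'   `NULL` = automatic (`1e-8 * mean diagonal`, escalated if needed, logged
#'   in the model).
#' @return a `reducer_model` with `class_axes = 1`.
#' @export
fit_lda_hybrid <- function(X, labels, k, ridge = NULL) {
  Z <- standardize_features(X)
  p <- ncol(Z); n <- nrow(Z)
  cls <- sort(unique(labels))
  if (length(cls) != 2) abort_sf12("fit_lda_hybrid requires exactly 2 classes")
  if (any(table(labels) < 2)) abort_sf12("every class must have at least 2 members")
  if (k < 1 || k > min(n - 1, p)) {
    abort_sf12(sprintf("k must be in 1..min(n-1, p) = %d", min(n - 1, p)))
  }
  Z0 <- Z[labels == cls[1], , drop = FALSE]
  Z1 <- Z[labels == cls[2], , drop = FALSE]
  Sw <- ((nrow(Z0) - 1) * stats::cov(Z0) + (nrow(Z1) - 1) * stats::cov(Z1)) / (n - 2)
  dmu <- colMeans(Z1) - colMeans(Z0)
  used_ridge <- 0
  w <- tryCatch(solve(Sw, dmu), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w)) || rcond(Sw) < 1e-12) {
    used_ridge <- if (is.null(ridge)) 1e-8 * mean(diag(Sw)) else ridge
    repeat {
      w <- tryCatch(solve(Sw + diag(used_ridge, p), dmu), error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) break
      used_ridge <- used_ridge * 100
    }
  }
  w <- w / sqrt(sum(w^2))
  axes <- matrix(w, p, 1)
  if (k > 1) {
    Proj <- diag(p) - w %*% t(w)
    eg <- eigen(stats::cov(Z %*% Proj), symmetric = TRUE)
    comp <- Proj %*% eg$vectors[, seq_len(k - 1), drop = FALSE]
    comp <- qr.Q(qr(comp))[, seq_len(k - 1), drop = FALSE]
    axes <- cbind(axes, comp)
  }
  rownames(axes) <- colnames(Z)
  build_reducer_model("LDA_hybrid", Z, axes, k, class_axes = 1L,
                      center = attr(Z, "center"), scale = attr(Z, "scale"),
                      extra = list(classes = cls, ridge = used_ridge))
}

#' Fit any of the five reducers by name
#'
#' Uniform entry point used by the benchmark and pipeline: `fit(X[, labels],
#' k)` returns a `reducer_model`; scores come from [predict.reducer_model()].
#'
#' @param method one of `"pca"`, `"kpca"`, `"gpca"`, `"ccpca"`, `"lda"`.
#' @inheritParams fit_ccpca
#' @param ... passed to the specific fitter.
#' @export
fit_reducer <- function(method = c("pca", "kpca", "gpca", "ccpca", "lda"),
                        X, k, labels = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    pca = fit_pca(X, k),
    kpca = fit_kpca(X, k, ...),
    gpca = fit_gpca(X, k, ...),
    ccpca = {
      if (is.null(labels)) abort_sf12("ccpca requires labels")
      fit_ccpca(X, labels, k, ...)
    },
    lda = {
      if (is.null(labels)) abort_sf12("lda requires labels")
      fit_lda_hybrid(X, labels, k, ...)
    })
}

#' Cumulative percentage of variance explained by the first k components
#'
#' @param model a `reducer_model`.
#' @param k number of leading components to sum.
#' @return percentage (0-100) rounded to two decimals, as displayed in
#'   variance-comparison tables.
#' @export
variance_explained_k <- function(model, k) {
  if (k < 1 || k > length(model$variance_explained)) {
    abort_sf12(sprintf("k must be in 1..%d (number of fitted axes)",
                       length(model$variance_explained)))
  }
  round(100 * sum(model$variance_explained[seq_len(k)]), 2)
}

#' Rank features by discriminant power
#'
#' For a supervised reducer (centroid-class PCA or the LDA hybrid), scores
#' each feature as the sum over retained components of |loading| x the
#' component's variance-explained fraction. Class-oriented components occupy
#' the leading positions of the model, so they are always retained first.
#' Ties break deterministically by feature name.
#'
#' @param model a supervised `reducer_model`.
#' @param components which components to sum over (default: all fitted).
#' @return data.frame `feature`, `power`, sorted descending.
#' @export
rank_discriminant_power <- function(model, components = seq_len(model$k)) {
  if (model$class_axes < 1L) {
    abort_sf12("discriminant-power ranking needs a supervised model (ccpca or lda); fit one first")
  }
  L <- abs(model$loadings[, components, drop = FALSE])
  w <- model$variance_explained[components]
  power <- as.numeric(L %*% w)
  ord <- order(-power, model$feature_names)
  data.frame(feature = model$feature_names[ord], power = power[ord],
             row.names = NULL)
}

#' Assign features to components by loading threshold
#'
#' A feature is assigned to the component where its |loading| is largest,
#' and only when that |loading| strictly exceeds the threshold (default
#' 0.7) — so a loading of exactly 0.7 is excluded and each feature appears
#' in at most one component's list.
#'
#' @param model a `reducer_model` with loadings.
#' @param threshold strict |loading| cut-off, default 0.7.
#' @return list of class `feature_assignment`: `assignment` (per-component
#'   character vectors), `selected` (union, in feature order), `threshold`.
#' @export
assign_features <- function(model, threshold = 0.7) {
  L <- model$loadings
  if (is.null(L)) abort_sf12("model has no loadings")
  k <- ncol(L)
  assignment <- stats::setNames(vector("list", k), paste0("component_", seq_len(k)))
  for (j in seq_len(k)) assignment[[j]] <- character(0)
  for (i in seq_len(nrow(L))) {
    li <- abs(L[i, ])
    j <- which.max(li)            # ties: first (lowest-index) component wins
    if (is.finite(li[j]) && li[j] > threshold) {
      assignment[[j]] <- c(assignment[[j]], rownames(L)[i])
    }
  }
  structure(list(assignment = assignment,
                 selected = rownames(L)[rownames(L) %in% unlist(assignment)],
                 threshold = threshold),
            class = "feature_assignment")
}

#' Variance-comparison table across the five reducers
#'
#' Fits all five methods at the same component count and tabulates the
#' cumulative percentage of variance explained — the model-selection view
#' used to pick the supervised reducer for downstream analysis.
#'
#' @param X feature matrix; `labels` binary outcome for the supervised
#'   methods.
#' @param labels class labels.
#' @param k component count (default 4).
#' @param gpca_seed seed for the stochastic-gradient fitter.
#' @return list: `table` (method, pct_variance_explained), `models` (the five
#'   fitted `reducer_model`s).
#' @export
compare_reducers <- function(X, labels, k = 4, gpca_seed = 42L) {
  models <- list(
    PCA = fit_pca(X, k),
    KPCA = fit_kpca(X, k),
    GPCA = fit_gpca(X, k, seed = gpca_seed),
    CCPCA = fit_ccpca(X, labels, k),
    LDA = fit_lda_hybrid(X, labels, k)
  )
  tab <- data.frame(
    method = names(models),
    pct_variance_explained = vapply(models, variance_explained_k, 0, k = k),
    row.names = NULL
  )
  list(table = tab, models = models, k = k)
}

#' Eigenvalue / variance table for a fitted reducer
#'
#' Per-component eigenvalue analogue, percent of total variance, and the two
#' cumulative columns; cumulative values are computed from the per-component
#' columns, never stored independently.
#'
#' @param model a `reducer_model`.
#' @return data.frame `component, eigenvalue, pct_variance, cumulative_eigenvalue,
#'   cumulative_pct`.
#' @export
eigenvalue_table <- function(model) {
  ev <- model$axis_variances
  pv <- 100 * model$variance_explained
  data.frame(component = seq_along(ev),
             eigenvalue = round(ev, 2),
             pct_variance = round(pv, 2),
             cumulative_eigenvalue = round(cumsum(ev), 2),
             cumulative_pct = round(cumsum(pv), 2))
}
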