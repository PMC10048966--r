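# dimensionality reducers: oracle equivalence, geometry, variance accounting

test_that("standardize_features is idempotent and drops constant columns", {
  set.seed(1)
  X <- matrix(rnorm(30 * 3), 30, 3)
  Z <- standardize_features(X)
  Z2 <- standardize_features(Z)
  expect_equal(unname(Z2[, ]), unname(Z[, ]), tolerance = 1e-12)
  Xc <- cbind(X, const = 5)
  expect_warning(Zc <- standardize_features(Xc), "constant")
  expect_equal(ncol(Zc), 3)
  expect_error(standardize_features(matrix(1, 5, 2)), "constant")
  # 3x2 hand matrix vs hand-computed z-scores
  H <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2)
  Zh <- standardize_features(H)
  expect_equal(unname(Zh[, 1]), (c(1, 2, 3) - 2) / 1)
  expect_equal(unname(Zh[, 2]), (c(10, 20, 60) - 30) / sd(c(10, 20, 60)))
})

test_that("PCA matches a dense eigendecomposition oracle", {
  set.seed(7)
  X <- matrix(rnorm(50 * 6), 50, 6)
  m <- fit_pca(X, 4)
  eg <- eigen(cov(scale(X)), symmetric = TRUE)     # independent oracle
  for (j in 1:4) expect_lt(angle_deg(m$axes[, j], eg$vectors[, j]), 1e-4)
  expect_equal(m$axis_variances, eg$values[1:4], tolerance = 1e-10)
  expect_equal(m$variance_explained, eg$values[1:4] / sum(eg$values),
               tolerance = 1e-10)
  expect_error(fit_pca(X, 7))
  # rank-1 data: one component explains everything
  line <- outer(rnorm(40), c(1, 2, -1))
  m1 <- fit_pca(line, 1)
  expect_equal(m1$variance_explained, 1, tolerance = 1e-10)
  # isotropic 2-D sample: roughly equal split
  iso <- matrix(rnorm(4000), 2000, 2)
  expect_equal(fit_pca(iso, 2)$variance_explained, c(0.5, 0.5), tolerance = 0.05)
})

test_that("PCA and GPCA agree with the eigen oracle across 20 seeds", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(50 * 6), 50, 6)
    m <- fit_pca(X, 4)
    g <- fit_gpca(X, 4, seed = s + 1000)
    for (j in 1:4) expect_lt(angle_deg(g$axes[, j], m$axes[, j]), 2)
  }
})

test_that("GPCA handles separated spectra, rank-1 data, and seed replicates", {
  set.seed(2)
  Y <- matrix(rnorm(500 * 3), 500, 3) %*% diag(sqrt(c(5, 1, 0.1)))
  mp <- fit_pca(Y, 3)
  gp <- fit_gpca(Y, 3, seed = 11)
  for (j in 1:3) expect_lt(angle_deg(gp$axes[, j], mp$axes[, j]), 2)
  expect_true(all(gp$convergence$converged))
  line <- outer(rnorm(60), c(2, -1, 1))
  g1 <- fit_gpca(line, 1, seed = 3)
  expect_equal(g1$variance_explained, 1, tolerance = 1e-6)
  ga <- fit_gpca(Y, 2, seed = 21)
  gb <- fit_gpca(Y, 2, seed = 22)
  for (j in 1:2) expect_lt(angle_deg(ga$axes[, j], gb$axes[, j]), 1)
})

test_that("kernel PCA reduces to PCA for the linear kernel and at large bandwidth", {
  set.seed(3)
  X <- matrix(rnorm(60 * 4), 60, 4)
  m <- fit_pca(X, 3)
  kl <- fit_kpca(X, 3, kernel = "linear")
  expect_equal(kl$variance_explained, m$variance_explained, tolerance = 1e-8)
  kb <- fit_kpca(X, 3, kernel = "rbf", sigma = 1e3)
  expect_equal(kb$variance_explained, kl$variance_explained, tolerance = 1e-4)
})

test_that("RBF kernel PCA separates concentric circles", {
  set.seed(7)
  n <- 150
  r <- rep(c(1, 3), each = n / 2)
  th <- runif(n, 0, 2 * pi)
  X <- cbind(r * cos(th), r * sin(th)) + matrix(rnorm(2 * n, 0, 0.05), n, 2)
  m <- fit_kpca(X, 2, sigma = 0.5)
  sc <- sweep(m$alpha, 2, sqrt(m$lambda), "*")
  sil <- cluster::silhouette(rep(1:2, each = n / 2), dist(sc))
  expect_gt(mean(sil[, 3]), 0.5)
  # out-of-sample transform agrees with training scores
  tr_scores <- predict(m, X)
  expect_equal(unname(tr_scores), unname(sc), tolerance = 1e-6)
})

test_that("CCPCA finds the centroid direction and degrades gracefully", {
  set.seed(1)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == 1, 1] <- X[y == 1, 1] + 6
  m <- fit_ccpca(X, y, 3)
  expect_lt(angle_deg(m$axes[, 1], c(1, 0, 0, 0)), 5)
  expect_equal(m$class_axes, 1L)
  # single class: equals plain PCA up to sign
  expect_warning(m1 <- fit_ccpca(X, rep(0, n), 3), "single class")
  mp <- fit_pca(X, 3)
  for (j in 1:3) expect_lt(angle_deg(m1$axes[, j], mp$axes[, j]), 1e-3)
  # tiny class rejected
  expect_error(fit_ccpca(X, c(1, rep(0, n - 1)), 2), "at least 2")
})

test_that("supervised reduction beats PCA when class structure is off-variance", {
  set.seed(9)
  n <- 400
  shared <- rnorm(n)
  X <- cbind(f1 = shared + rnorm(n, 0, 0.2),
             f2 = shared + rnorm(n, 0, 0.2),
             f3 = rnorm(n))
  y <- rep(0:1, each = n / 2)
  X[y == 1, 3] <- X[y == 1, 3] + 2.5
  pc <- fit_pca(X, 1)
  cc <- fit_ccpca(X, y, 1)
  expect_gt(angle_deg(pc$axes[, 1], cc$axes[, 1]), 30)
  acc1 <- function(s) {
    df <- data.frame(s = s, y = y)
    p <- predict(glm(y ~ s, df, family = binomial), type = "response")
    mean((p > 0.5) == y)
  }
  # brute-force check of the downstream advantage on one component
  expect_gt(acc1(predict(cc, X)[, 1]), acc1(predict(pc, X)[, 1]) + 0.2)
})

test_that("LDA hybrid matches closed-form Fisher and the centroid axis", {
  set.seed(4)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  # isotropic within-class noise: Fisher axis parallels the centroid axis
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == 1, 1] <- X[y == 1, 1] + 6
  l <- fit_lda_hybrid(X, y, 3)
  cc <- fit_ccpca(X, y, 3)
  expect_lt(angle_deg(l$axes[, 1], cc$axes[, 1]), 5)
  expect_equal(length(fit_lda_hybrid(X, y, 1)$variance_explained), 1L)
  # anisotropic noise: matches the closed-form solution on standardized data
  A <- chol(diag(c(4, 1, 1, 0.5)))
  X2 <- matrix(rnorm(n * 4), n, 4) %*% A
  X2[y == 1, ] <- sweep(X2[y == 1, , drop = FALSE], 2, c(2, 1, 0, 0), "+")
  l2 <- fit_lda_hybrid(X2, y, 2)
  Z <- scale(X2)
  Z0 <- Z[y == 0, ]; Z1 <- Z[y == 1, ]
  Sw <- ((nrow(Z0) - 1) * cov(Z0) + (nrow(Z1) - 1) * cov(Z1)) / (n - 2)
  wf <- solve(Sw, colMeans(Z1) - colMeans(Z0))
  expect_lt(angle_deg(l2$axes[, 1], wf), 1e-6)
})

test_that("axes are orthonormal and variance is conserved", {
  set.seed(6)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- rep(0:1, each = 40)
  X[y == 1, 2] <- X[y == 1, 2] + 1.5
  models <- list(fit_pca(X, 5), fit_gpca(X, 4, seed = 2),
                 fit_ccpca(X, y, 4), fit_lda_hybrid(X, y, 4))
  for (m in models) {
    G <- crossprod(m$axes)
    expect_lt(max(abs(G - diag(ncol(m$axes)))), 1e-8)
    expect_true(all(m$variance_explained >= 0 & m$variance_explained <= 1))
    expect_lte(sum(m$variance_explained), 1 + 1e-8)
  }
  expect_equal(sum(fit_pca(X, 5)$variance_explained), 1, tolerance = 1e-10)
})

test_that("variance_explained_k reproduces printed cumulative arithmetic", {
  m <- stub_model(ve = c(0.3155, 0.2755, 0.1533, 0.0743))
  expect_equal(variance_explained_k(m, 2), 59.10)
  expect_error(variance_explained_k(m, 5), "fitted axes")
  set.seed(8)
  full <- fit_pca(matrix(rnorm(200), 50, 4), 4)
  expect_equal(variance_explained_k(full, 4), 100, tolerance = 0.01)
  line <- outer(rnorm(30), c(1, 3))
  expect_equal(variance_explained_k(fit_pca(line, 1), 1), 100)
})

test_that("eigenvalue_table computes cumulative columns from per-component ones", {
  m <- stub_model(ve = c(0.3155, 0.2755, 0.1533, 0.0743),
                  axis_variances = c(3.73, 2.33, 2.19, 1.44))
  tab <- eigenvalue_table(m)
  expect_equal(tab$cumulative_eigenvalue, c(3.73, 6.06, 8.25, 9.69))
  expect_equal(tab$cumulative_pct, c(31.55, 59.10, 74.43, 81.86))
})

test_that("discriminant-power ranking orders features and demands supervision", {
  L <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(c("a", "b"), NULL))
  m <- stub_model(ve = 0.6, class_axes = 1L, loadings = L)
  expect_equal(rank_discriminant_power(m)$feature[1], "a")
  expect_error(rank_discriminant_power(stub_model(ve = 0.6, loadings = L)),
               "supervised")
  # constructed fixture: only feature 3 separates the classes
  set.seed(12)
  n <- 600
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[y == 1, 3] <- X[y == 1, 3] + 3
  # brute-force per-feature class separation confirms the fixture
  tstats <- abs(vapply(1:4, function(j) t.test(X[y == 1, j], X[y == 0, j])$statistic, 0))
  expect_equal(which.max(tstats), 3L)
  r <- rank_discriminant_power(fit_ccpca(X, y, 2))
  expect_equal(r$feature[1], "f3")
  # permutation invariance of the ranking content
  perm <- c(3, 1, 4, 2)
  r2 <- rank_discriminant_power(fit_ccpca(X[, perm], y, 2))
  expect_equal(r2$feature, r$feature)
  expect_equal(r2$power, r$power, tolerance = 1e-8)
})

test_that("feature assignment applies the strict 0.7 rule and unique claims", {
  L <- matrix(c(0.70, -0.85, 0.80, 0.1,
                0.10, 0.20, 0.82, 0.2), 4, 2,
              dimnames = list(c("w", "x", "y", "z"), NULL))
  m <- stub_model(ve = c(0.4, 0.2), loadings = L)
  fa <- assign_features(m, threshold = 0.7)
  expect_false("w" %in% unlist(fa$assignment))      # 0.70 exactly: excluded
  expect_true("x" %in% fa$assignment$component_1)   # |-0.85| included
  # y loads > 0.7 on both components: claimed by the larger |loading| only
  expect_true("y" %in% fa$assignment$component_2)
  expect_false("y" %in% fa$assignment$component_1)
  expect_false("z" %in% unlist(fa$assignment))
  expect_setequal(fa$selected, c("x", "y"))
})

test_that("compare_reducers tabulates all five methods at a common k", {
  cal <- calibrated_cfg()
  co <- generate_cohort(cal, seed = 44)
  feats <- cohort_features(co)
  cmp <- compare_reducers(feats$X, feats$labels, k = 4, gpca_seed = 5)
  expect_setequal(cmp$table$method, c("PCA", "KPCA", "GPCA", "CCPCA", "LDA"))
  expect_true(all(cmp$table$pct_variance_explained > 0 &
                    cmp$table$pct_variance_explained <= 100))
  # GPCA approximates PCA, so their cumulative variance agrees closely
  expect_lt(abs(cmp$table$pct_variance_explained[cmp$table$method == "GPCA"] -
                  cmp$table$pct_variance_explained[cmp$table$method == "PCA"]), 1)
})
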