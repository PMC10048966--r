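# Internal classifier zoo for the benchmark grid.
#
# Each fitter takes a numeric training matrix (already standardized by the
# benchmark harness), 0/1 labels and a hyperparameter list, and returns a
# predict(Xnew) closure yielding 0/1 labels. CART, the RBF-kernel SVM (dual
# QP via quadprog), the one-hidden-layer MLP and Gaussian naive Bayes are
# implemented here; k-NN uses FNN and logistic regression uses base glm.

fit_classifier <- function(name, X, y, hyper = list(), seed = 1L) {
  switch(name,
    regg = fit_clf_logistic(X, y),
    knn  = fit_clf_knn(X, y, k = hyper$knn_k %||% 5L),
    svm  = fit_clf_svm(X, y, C = hyper$svm_C %||% 1,
                       gamma = hyper$svm_gamma %||% (1 / ncol(X))),
    mlp  = fit_clf_mlp(X, y, hidden = hyper$mlp_hidden %||% 16L,
                       maxit = hyper$mlp_maxit %||% 1000L, seed = seed),
    cart = fit_clf_cart(X, y,
                        max_depth = hyper$cart_max_depth %||% 5L,
                        min_leaf = hyper$cart_min_leaf %||% max(2L, ceiling(0.05 * nrow(X)))),
    gnb  = fit_clf_gnb(X, y),
    abort_sf12(sprintf("unknown classifier '%s'", name))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_clf_logistic <- function(X, y) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  function(Xnew) {
    p <- suppressWarnings(stats::predict(fit, newdata = as.data.frame(Xnew),
                                         type = "response"))
    as.integer(p > 0.5)
  }
}

fit_clf_knn <- function(X, y, k = 5L) {
  k <- min(k, nrow(X))
  function(Xnew) {
    as.integer(as.character(FNN::knn(train = X, test = Xnew,
                                     cl = factor(y), k = k)))
  }
}

# soft-margin RBF SVM solved in the dual with quadprog:
#   max sum(alpha) - 1/2 alpha' (yy' * K) alpha,  0 <= alpha <= C, y'alpha = 0
fit_clf_svm <- function(X, y, C = 1, gamma = 1 / ncol(X)) {
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  sigma <- sqrt(1 / (2 * gamma))
  K <- rbf_kernel(X, X, sigma)
  Dmat <- (ys %o% ys) * K + diag(1e-8, n)
  dvec <- rep(1, n)
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  margin_sv <- sv & alpha < C - 1e-6
  f_no_b <- drop(K %*% (alpha * ys))
  b <- if (any(margin_sv)) mean(ys[margin_sv] - f_no_b[margin_sv])
       else mean(ys[sv] - f_no_b[sv])
  Xsv <- X[sv, , drop = FALSE]
  coef_sv <- (alpha * ys)[sv]
  function(Xnew) {
    f <- drop(rbf_kernel(as.matrix(Xnew), Xsv, sigma) %*% coef_sv) + b
    as.integer(f > 0)
  }
}

# single-hidden-layer tanh MLP with sigmoid output, cross-entropy loss,
# full-batch gradient descent with momentum
fit_clf_mlp <- function(X, y, hidden = 16L, maxit = 1000L, lr = 0.05,
                        momentum = 0.9, l2 = 1e-4, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(1 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
    b2 <- 0
    vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
    for (it in seq_len(maxit)) {
      H <- tanh(sweep(X %*% W1, 2, b1, "+"))
      z <- drop(H %*% W2) + b2
      phat <- stats::plogis(z)
      delta2 <- (phat - y) / n
      gW2 <- t(H) %*% delta2 + l2 * W2
      gb2 <- sum(delta2)
      dH <- (delta2 %o% drop(W2)) * (1 - H^2)
      gW1 <- t(X) %*% dH + l2 * W1
      gb1 <- colSums(dH)
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    force(W1); force(b1); force(W2); force(b2)
  })
  function(Xnew) {
    H <- tanh(sweep(as.matrix(Xnew) %*% W1, 2, b1, "+"))
    as.integer(drop(H %*% W2) + b2 > 0)
  }
}

fit_clf_gnb <- function(X, y, var_floor = 1e-9) {
  cls <- sort(unique(y))
  stats_by <- lapply(cls, function(c0) {
    Xi <- X[y == c0, , drop = FALSE]
    list(prior = log(nrow(Xi) / nrow(X)),
         mu = colMeans(Xi),
         v = pmax(apply(Xi, 2, stats::var), var_floor))
  })
  names(stats_by) <- as.character(cls)
  function(Xnew) {
    Xnew <- as.matrix(Xnew)
    ll <- vapply(stats_by, function(s) {
      z2 <- sweep(Xnew, 2, s$mu, "-")^2
      s$prior + rowSums(-0.5 * (log(2 * pi * rep(1, nrow(Xnew)) %o% s$v) +
                                  sweep(z2, 2, s$v, "/")))
    }, numeric(nrow(Xnew)))
    ll <- matrix(ll, nrow = nrow(Xnew))
    cls[max.col(ll, ties.method = "first")]
  }
}

fit_clf_cart <- function(X, y, max_depth = 5L, min_leaf = 2L) {
  df <- as.data.frame(X)
  tree <- grow_cart(df, y, max_depth = max_depth, min_leaf = min_leaf)
  function(Xnew) {
    risk <- predict_cart_risk(tree, as.data.frame(Xnew))
    as.integer(risk > 0.5)
  }
}
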