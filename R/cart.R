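# In-package CART: greedy recursive binary partitioning with Gini impurity.
# Splits are "feature < threshold" (left) vs ">= threshold" (right), with
# thresholds at midpoints between consecutive distinct values. Deterministic:
# ties on impurity gain break by column order, then by smaller threshold.
# Every node carries n, the class-1 count, the risk (class-1 proportion) and
# the risk delta against its parent — the a-priori / a-posteriori semantics
# of a risk tree.

gini <- function(n1, n) {
  if (n == 0) return(0)
  p <- n1 / n
  2 * p * (1 - p)
}

# best split of one node; returns NULL if no admissible split exists
best_split <- function(df, y, min_leaf) {
  n <- length(y)
  parent_imp <- gini(sum(y), n)
  best <- NULL
  for (j in seq_along(df)) {
    x <- df[[j]]
    ord <- order(x, method = "radix")
    xs <- x[ord]; ys <- y[ord]
    cum1 <- cumsum(ys)
    distinct <- which(diff(xs) > 0)       # split after position i
    for (i in distinct) {
      nl <- i; nr <- n - i
      if (nl < min_leaf || nr < min_leaf) next
      imp <- (nl * gini(cum1[i], nl) + nr * gini(cum1[n] - cum1[i], nr)) / n
      gain <- parent_imp - imp
      thr <- (xs[i] + xs[i + 1]) / 2
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12 ||
           (abs(gain - best$gain) <= 1e-12 && j == best$col && thr < best$threshold))) {
        best <- list(col = j, feature = names(df)[j], threshold = thr,
                     gain = gain)
      }
    }
  }
  best
}

grow_cart <- function(df, y, max_depth = 3L, min_leaf = 2L,
                      depth = 0L, parent_risk = NA_real_, id = 1L) {
  n <- length(y)
  n1 <- sum(y)
  risk <- n1 / n
  node <- list(id = id, depth = depth, n = n, n1 = as.integer(n1),
               risk = risk,
               delta = if (is.na(parent_risk)) NA_real_ else risk - parent_risk,
               split = NULL, children = NULL)
  if (depth >= max_depth || n1 == 0L || n1 == n || n < 2L * min_leaf) {
    return(node)
  }
  sp <- best_split(df, y, min_leaf)
  if (is.null(sp)) return(node)
  left_idx <- df[[sp$col]] < sp$threshold
  node$split <- list(feature = sp$feature, threshold = sp$threshold,
                     gain = sp$gain)
  left <- grow_cart(df[left_idx, , drop = FALSE], y[left_idx],
                    max_depth, min_leaf, depth + 1L, risk, id * 2L)
  right <- grow_cart(df[!left_idx, , drop = FALSE], y[!left_idx],
                     max_depth, min_leaf, depth + 1L, risk, id * 2L + 1L)
  node$children <- list(left = left, right = right)
  node
}

predict_cart_risk <- function(node, df) {
  n <- nrow(df)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (is.null(node$children)) {
      out[idx] <<- node$risk
      return(invisible())
    }
    go_left <- df[[node$split$feature]][idx] < node$split$threshold
    if (any(go_left)) rec(node$children$left, idx[go_left])
    if (any(!go_left)) rec(node$children$right, idx[!go_left])
  }
  if (n > 0) rec(node, seq_len(n))
  out
}

# flatten the node hierarchy, parents before children
cart_nodes <- function(node) {
  acc <- list()
  rec <- function(nd, path) {
    nd2 <- nd
    nd2$children <- NULL
    nd2$path <- path
    acc[[length(acc) + 1L]] <<- nd2
    if (!is.null(nd$children)) {
      cond_l <- sprintf("%s < %g", nd$split$feature, nd$split$threshold)
      cond_r <- sprintf("%s >= %g", nd$split$feature, nd$split$threshold)
      rec(nd$children$left, c(path, cond_l))
      rec(nd$children$right, c(path, cond_r))
    }
  }
  rec(node, character(0))
  acc
}
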