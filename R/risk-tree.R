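#' Configuration for the CART risk tree
#'
#' @param max_depth maximum split depth (default 3, matching a compact
#'   clinical risk tree).
#' @param min_leaf_frac minimum leaf size as a fraction of n (default 0.05).
#' @param criterion impurity criterion; only `"gini"` is implemented.
#' @param features character vector of feature columns to split on.
#' @return a `tree_config` list.
#' @export
tree_config <- function(max_depth = 3L, min_leaf_frac = 0.05,
                        criterion = "gini", features = NULL) {
  if (max_depth < 1) abort_sf12("max_depth must be >= 1",
                                class = "sf12risk_config_error")
  if (!identical(criterion, "gini")) {
    abort_sf12("only the gini criterion is implemented",
               class = "sf12risk_config_error")
  }
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf_frac = min_leaf_frac,
                 criterion = criterion, features = features),
            class = "tree_config")
}

#' Fit a CART risk tree
#'
#' Recursive binary partitioning (Gini impurity) of the selected features
#' against the binary depression-risk label. Every node is annotated with its
#' sample count, risk (class-1 proportion — the a-priori risk at the root,
#' a-posteriori below), and the signed risk change against its parent.
#' Deterministic given data and config. Single-class data yields a root-only
#' tree with a warning.
#'
#' @param data data.frame containing the feature columns.
#' @param labels 0/1 outcome vector.
#' @param cfg a [tree_config()]; `cfg$features` defaults to all columns of
#'   `data`.
#' @return an object of class `risk_tree`: nested node list plus metadata.
#' @export
fit_risk_tree <- function(data, labels, cfg = tree_config()) {
  if (!all(labels %in% c(0, 1))) abort_sf12("labels must be 0/1")
  feats <- cfg$features %||% names(data)
  missing_f <- setdiff(feats, names(data))
  if (length(missing_f) > 0) {
    abort_sf12(sprintf("selected feature(s) not in data: %s",
                       paste(missing_f, collapse = ", ")))
  }
  if (length(feats) == 0) abort_sf12("feature list is empty",
                                     class = "sf12risk_config_error")
  df <- data[, feats, drop = FALSE]
  if (any(!vapply(df, is.numeric, TRUE))) {
    abort_sf12("risk-tree features must be numeric (encode binaries as 0/1)")
  }
  n <- nrow(df)
  min_leaf <- max(2L, ceiling(cfg$min_leaf_frac * n))
  if (length(unique(labels)) < 2) {
    warning("single-class labels: returning a root-only tree")
  }
  root <- grow_cart(df, as.integer(labels), max_depth = cfg$max_depth,
                    min_leaf = min_leaf)
  structure(list(root = root, config = cfg, features = feats,
                 n = n, min_leaf = min_leaf,
                 prevalence = mean(labels)),
            class = "risk_tree")
}

#' @export
print.risk_tree <- function(x, ...) {
  cat(render_tree(x, format = "text"))
  invisible(x)
}

#' Predict node risks for new patients
#' @param object a `risk_tree`.
#' @param newdata data.frame with the tree's feature columns.
#' @param ... unused.
#' @return numeric vector of leaf risks (class-1 proportions).
#' @export
predict.risk_tree <- function(object, newdata, ...) {
  predict_cart_risk(object$root, newdata[, object$features, drop = FALSE])
}

#' Per-node risk report along tree paths
#'
#' One row per node, parents before children: the condition chain from the
#' root, sample count, risk as a percentage (two decimals), and the signed
#' risk delta against the parent (blank at the root — the a-priori risk).
#' The highest-risk leaf is flagged.
#'
#' @param tree a `risk_tree`.
#' @return data.frame `node_id, depth, condition, n, risk_pct, delta_pct,
#'   is_leaf, highest_risk_leaf`.
#' @export
path_risk_report <- function(tree) {
  nodes <- cart_nodes(tree$root)
  rep_df <- data.frame(
    node_id = vapply(nodes, function(nd) nd$id, 0L),
    depth = vapply(nodes, function(nd) nd$depth, 0L),
    condition = vapply(nodes, function(nd) {
      if (length(nd$path) == 0) "(all patients)" else paste(nd$path, collapse = " & ")
    }, ""),
    n = vapply(nodes, function(nd) nd$n, 0L),
    risk_pct = vapply(nodes, function(nd) round(100 * nd$risk, 2), 0),
    delta_pct = vapply(nodes, function(nd) {
      if (is.na(nd$delta)) NA_real_ else round(100 * nd$delta, 2)
    }, 0),
    is_leaf = vapply(nodes, function(nd) is.null(nd$split), TRUE),
    row.names = NULL
  )
  leaf_risks <- ifelse(rep_df$is_leaf, rep_df$risk_pct, -Inf)
  rep_df$highest_risk_leaf <- seq_len(nrow(rep_df)) == which.max(leaf_risks)
  rep_df
}

#' Check count and risk conservation of a risk tree
#'
#' Verifies, at every internal node, that child sample counts sum to the
#' parent's, that class-1 counts are conserved (equivalently risk(parent) =
#' sum over children of risk x n / n(parent), exactly in counts), and that
#' every node's risk x n is an integer count.
#'
#' @param tree a `risk_tree` (or a deserialized one).
#' @return list `pass` (logical) and `violations` (data.frame of offending
#'   node ids and reasons, empty when pass).
#' @export
check_conservation <- function(tree) {
  violations <- data.frame(node_id = integer(0), reason = character(0))
  rec <- function(nd) {
    if (abs(nd$risk * nd$n - nd$n1) > 1e-9) {
      violations <<- rbind(violations, data.frame(
        node_id = nd$id, reason = "risk x n is not the class-1 count"))
    }
    if (!is.null(nd$children)) {
      kids <- nd$children
      if (kids$left$n + kids$right$n != nd$n) {
        violations <<- rbind(violations, data.frame(
          node_id = nd$id, reason = "child sample counts do not sum to parent"))
      }
      if (kids$left$n1 + kids$right$n1 != nd$n1) {
        violations <<- rbind(violations, data.frame(
          node_id = nd$id, reason = "child class-1 counts do not sum to parent"))
      }
      rec(kids$left); rec(kids$right)
    }
  }
  rec(tree$root)
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Render a risk tree as text or DOT
#'
#' Node labels carry `condition | n | risk% | delta`. Output is
#' deterministic: rendering the same tree twice is byte-identical.
#'
#' @param tree a `risk_tree`.
#' @param format `"text"` or `"dot"`.
#' @return a single character string.
#' @export
render_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  nodes <- cart_nodes(tree$root)
  if (format == "text") {
    lines <- vapply(nodes, function(nd) {
      lab <- if (length(nd$path) == 0) "a-priori risk"
             else nd$path[length(nd$path)]
      d <- if (is.na(nd$delta)) "" else sprintf(" (%+0.2f%%)", 100 * nd$delta)
      sprintf("%s%s | n=%d | risk=%.2f%%%s",
              strrep("  ", nd$depth), lab, nd$n, 100 * nd$risk, d)
    }, "")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  decl <- vapply(nodes, function(nd) {
    cond <- if (length(nd$path) == 0) "all patients" else nd$path[length(nd$path)]
    d <- if (is.na(nd$delta)) "a priori" else sprintf("%+0.2f%%", 100 * nd$delta)
    sprintf("  n%d [label=\"%s | n=%d | %.2f%% | %s\", shape=box];",
            nd$id, cond, nd$n, 100 * nd$risk, d)
  }, "")
  edges <- character(0)
  for (nd in nodes) {
    if (nd$id > 1L) {
      edges <- c(edges, sprintf("  n%d -> n%d;", nd$id %/% 2L, nd$id))
    }
  }
  paste0("digraph risk_tree {\n", paste(decl, collapse = "\n"), "\n",
         paste(edges, collapse = "\n"), "\n}\n")
}

#' Serialize / deserialize a risk tree as JSON
#'
#' @param tree a `risk_tree`.
#' @param path file path; `tree_to_json` returns the JSON string invisibly
#'   and writes when `path` is given.
#' @return `tree_to_json`: JSON string; `tree_from_json`: a `risk_tree`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  payload <- list(root = tree$root,
                  config = unclass(tree$config),
                  features = tree$features, n = tree$n,
                  min_leaf = tree$min_leaf, prevalence = tree$prevalence)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  payload <- jsonlite::fromJSON(if (file.exists(path)) path else path,
                                simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix_node <- function(nd) {
    nd$n <- as.integer(nd$n); nd$n1 <- as.integer(nd$n1)
    nd$id <- as.integer(nd$id); nd$depth <- as.integer(nd$depth)
    nd$delta <- if (is.null(nd$delta) || length(nd$delta) != 1L) NA_real_
                else suppressWarnings(as.numeric(nd$delta))
    if (!is.null(nd$children)) {
      nd$children$left <- fix_node(nd$children$left)
      nd$children$right <- fix_node(nd$children$right)
    }
    nd
  }
  cfg <- payload$config
  structure(list(root = fix_node(payload$root),
                 config = structure(cfg, class = "tree_config"),
                 features = unlist(payload$features),
                 n = as.integer(payload$n),
                 min_leaf = as.integer(payload$min_leaf),
                 prevalence = payload$prevalence),
            class = "risk_tree")
}
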