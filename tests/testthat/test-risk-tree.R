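# CART risk tree: splits, conservation, reporting, rendering, serialization

test_that("a separable rule is recovered as a depth-1 tree", {
  set.seed(1)
  VT <- runif(400, 0, 100)
  labels <- as.integer(VT < 40)
  tr <- fit_risk_tree(data.frame(VT = VT, noise = rnorm(400)), labels,
                      tree_config(max_depth = 1))
  rep <- path_risk_report(tr)
  expect_equal(nrow(rep), 3)
  split_cond <- rep$condition[rep$node_id == 2]
  expect_match(split_cond, "^VT < ")
  thr <- as.numeric(sub("VT < ", "", split_cond))
  expect_lt(abs(thr - 40), 2)
  expect_setequal(rep$risk_pct[rep$is_leaf], c(100, 0))
})

test_that("degenerate labels give a root-only tree", {
  df <- data.frame(x = rnorm(50))
  expect_warning(tr <- fit_risk_tree(df, rep(0L, 50)), "single-class")
  rep <- path_risk_report(tr)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$risk_pct, 0)
  expect_true(is.na(rep$delta_pct))     # a-priori node has no delta
})

test_that("count conservation and child-risk bracketing hold on fitted trees", {
  cal <- calibrated_cfg()
  for (s in 1:5) {
    co <- generate_cohort(cal, seed = 100 + s)
    tr <- fit_risk_tree(co, co$depression_risk,
                        tree_config(features = c("VT", "RE", "nyha_high",
                                                 "heart_failure")))
    expect_true(check_conservation(tr)$pass)
    # min child risk <= parent risk <= max child risk, exactly
    check_bracket <- function(nd) {
      if (is.null(nd$children)) return(invisible(TRUE))
      risks <- c(nd$children$left$risk, nd$children$right$risk)
      expect_lte(min(risks), nd$risk + 1e-12)
      expect_gte(max(risks), nd$risk - 1e-12)
      check_bracket(nd$children$left)
      check_bracket(nd$children$right)
    }
    check_bracket(tr$root)
    # min-leaf contract: no empty leaves possible
    rep <- path_risk_report(tr)
    expect_true(all(rep$n[rep$is_leaf] >= tr$min_leaf))
  }
})

test_that("a corrupted child count fails conservation naming the node", {
  set.seed(2)
  df <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- as.integer(df$a > 0)
  tr <- fit_risk_tree(df, y, tree_config(max_depth = 2))
  bad <- tr
  bad$root$children$left$n <- bad$root$children$left$n + 1L
  res <- check_conservation(bad)
  expect_false(res$pass)
  expect_true(1L %in% res$violations$node_id)
})

test_that("path_risk_report prints two-decimal risks and signed deltas", {
  # hand-built nodes exercising the printed-arithmetic example:
  # parent risk 41/110 = 37.27%, child 40/121 = 33.06%, delta -4.21
  child <- list(id = 2L, depth = 1L, n = 121L, n1 = 40L, risk = 40 / 121,
                delta = 40 / 121 - 41 / 110, split = NULL, children = NULL)
  sib <- list(id = 3L, depth = 1L, n = 9L, n1 = 5L, risk = 5 / 9,
              delta = 5 / 9 - 41 / 110, split = NULL, children = NULL)
  root <- list(id = 1L, depth = 0L, n = 110L, n1 = 41L, risk = 41 / 110,
               delta = NA_real_,
               split = list(feature = "nyha_high", threshold = 0.5, gain = 0.01),
               children = list(left = child, right = sib))
  tree <- structure(list(root = root, config = tree_config(), features = "nyha_high",
                         n = 110L, min_leaf = 5L, prevalence = 41 / 110),
                    class = "risk_tree")
  rep <- path_risk_report(tree)
  expect_equal(rep$risk_pct[rep$node_id == 1], 37.27)
  expect_equal(rep$risk_pct[rep$node_id == 2], 33.06)
  expect_equal(rep$delta_pct[rep$node_id == 2], -4.21)
  expect_true(is.na(rep$delta_pct[rep$node_id == 1]))
  expect_equal(sum(rep$highest_risk_leaf), 1)
})

test_that("rendering is deterministic and DOT output is well-formed", {
  set.seed(3)
  df <- data.frame(u = rnorm(300), v = rnorm(300), w = rnorm(300))
  y <- as.integer(df$u + 0.5 * df$v + rnorm(300, 0, 0.5) > 0)
  tr <- fit_risk_tree(df, y, tree_config(max_depth = 3))
  expect_identical(render_tree(tr, "text"), render_tree(tr, "text"))
  dot <- render_tree(tr, "dot")
  expect_identical(dot, render_tree(tr, "dot"))
  expect_match(dot, "^digraph risk_tree \\{")
  expect_equal(sum(strsplit(dot, "")[[1]] == "{"),
               sum(strsplit(dot, "")[[1]] == "}"))
  # every edge endpoint is a declared node; at most 15 nodes at depth 3
  decl <- regmatches(dot, gregexpr("n[0-9]+ \\[", dot))[[1]]
  ids <- sub(" \\[", "", decl)
  expect_lte(length(ids), 15)
  edges <- regmatches(dot, gregexpr("n[0-9]+ -> n[0-9]+", dot))[[1]]
  endpoints <- unique(unlist(strsplit(edges, " -> ")))
  expect_true(all(endpoints %in% ids))
  # root-only tree renders a single node and no edges
  tr0 <- suppressWarnings(fit_risk_tree(df, rep(0L, 300)))
  dot0 <- render_tree(tr0, "dot")
  expect_false(grepl("->", dot0))
  expect_error(render_tree(tr, "svg"))
})

test_that("JSON serialization round-trips exactly", {
  set.seed(4)
  df <- data.frame(a = rnorm(200), b = rnorm(200))
  y <- as.integer(df$a - df$b > 0)
  tr <- fit_risk_tree(df, y, tree_config(max_depth = 2))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  tr2 <- tree_from_json(path)
  expect_true(check_conservation(tr2)$pass)
  expect_identical(render_tree(tr, "text"), render_tree(tr2, "text"))
  expect_identical(path_risk_report(tr), path_risk_report(tr2))
  expect_equal(predict(tr2, df), predict(tr, df))
})

test_that("prediction routes patients to their leaf risks", {
  set.seed(5)
  VT <- runif(300, 0, 100)
  y <- as.integer(VT < 37.5)
  tr <- fit_risk_tree(data.frame(VT = VT), y, tree_config(max_depth = 1))
  p <- predict(tr, data.frame(VT = c(10, 90)))
  expect_equal(p, c(1, 0))
})
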