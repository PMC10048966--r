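#' Build the modelling feature matrix from a scored cohort
#'
#' Default feature set: the eight SF-12 domain scores plus the clinical
#' covariates (age, sex, NYHA class, CCS class, heart failure, EUROscore).
#' The component summaries are excluded — MCS defines the outcome, and PCS
#' is a derived composite of the included domains.
#'
#' @param scored a scored cohort from [score_cohort()] / [generate_cohort()].
#' @param covariates covariate columns to include (only those present are
#'   used).
#' @return list `X` (numeric matrix), `labels` (0/1 vector).
#' @export
cohort_features <- function(scored,
                            covariates = c("age", "male", "nyha_high",
                                           "ccs_high", "heart_failure",
                                           "euroscore")) {
  cols <- c(sf12_domains(), intersect(covariates, names(scored)))
  missing_d <- setdiff(sf12_domains(), names(scored))
  if (length(missing_d) > 0) {
    abort_sf12(sprintf("scored cohort lacks domain column(s): %s",
                       paste(missing_d, collapse = ", ")))
  }
  X <- as.matrix(scored[, cols, drop = FALSE])
  if (!is.numeric(X)) abort_sf12("feature columns must be numeric")
  list(X = X, labels = scored$depression_risk)
}

#' Pipeline configuration
#'
#' @param input `list(mode = "synthetic")` or `list(mode = "csv", path = ...)`.
#' @param synthetic a [synthetic_config()].
#' @param coefficients a scoring-coefficient table.
#' @param bench a [bench_config()].
#' @param tree a [tree_config()].
#' @param k components for the reducer comparison (default 4).
#' @param loading_threshold strict |loading| cut-off for feature assignment.
#' @param calibrate calibrate the generator to the target prevalence before
#'   simulating (default TRUE in synthetic mode).
#' @param out_dir output directory for artifacts.
#' @param seed root seed; fans out to per-stage streams.
#' @export
pipeline_config <- function(input = list(mode = "synthetic", path = NULL),
                            synthetic = synthetic_config(),
                            coefficients = default_scoring_coefficients(),
                            bench = bench_config(repeats = 3L),
                            tree = tree_config(),
                            k = 4L, loading_threshold = 0.7,
                            calibrate = TRUE,
                            out_dir = tempfile("sf12risk_run_"),
                            seed = 1L) {
  if (!input$mode %in% c("synthetic", "csv")) {
    abort_sf12("input mode must be 'synthetic' or 'csv'",
               class = "sf12risk_config_error")
  }
  if (input$mode == "csv" && (is.null(input$path) || !file.exists(input$path))) {
    abort_sf12("csv input mode requires an existing input path",
               class = "sf12risk_config_error")
  }
  structure(list(input = input, synthetic = synthetic,
                 coefficients = coefficients, bench = bench, tree = tree,
                 k = as.integer(k), loading_threshold = loading_threshold,
                 calibrate = calibrate, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full depression-risk pipeline
#'
#' Stages: (1) generate a calibrated synthetic cohort or ingest and score a
#' cohort CSV; (2) SF-12 scoring, risk labels, prevalence summary; (3) fit
#' the five reducers at `k` components and tabulate variance explained,
#' eigenvalues, discriminant-power ranking, and the loading-threshold
#' feature assignment; (4) cross-validated classifier x component grid and
#' best-cell selection; (5) CART risk tree on the selected raw features with
#' path-risk report, DOT and JSON renderings; (6) a machine-readable run
#' manifest. Any stage failure aborts with the partial manifest on disk.
#'
#' @param cfg a [pipeline_config()].
#' @return list of in-memory results plus `manifest` (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("sf12risk")),
                   seed = cfg$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   input_mode = cfg$input$mode,
                   stages = list(), artifacts = character(0), warnings = character(0))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    write_manifest()
  }
  emit <- function(name) manifest$artifacts <<- c(manifest$artifacts, name)
  write_manifest()

  # stage 1-2: cohort + scoring
  if (cfg$input$mode == "synthetic") {
    syn <- cfg$synthetic
    if (cfg$calibrate && is.null(syn$calibration)) {
      syn <- calibrate_prevalence(syn, seed = child_seed(cfg$seed, "calibration"))
    }
    scored <- generate_cohort(syn, seed = child_seed(cfg$seed, "cohort"))
    note("cohort", mode = "synthetic", n = nrow(scored),
         mu_mental = syn$mu_mental,
         calibrated = !is.null(syn$calibration))
  } else {
    raw <- utils::read.csv(cfg$input$path, stringsAsFactors = FALSE)
    scored <- score_cohort(raw, coef = cfg$coefficients)
    note("cohort", mode = "csv", path = cfg$input$path, n = nrow(scored))
  }
  utils::write.csv(scored, file.path(cfg$out_dir, "scored_cohort.csv"),
                   row.names = FALSE)
  emit("scored_cohort.csv")
  summ <- summarize_cohort(scored)
  utils::write.csv(summ$table, file.path(cfg$out_dir, "domain_summary.csv"),
                   row.names = FALSE)
  emit("domain_summary.csv")
  note("scoring", n = summ$n, risk_count = summ$risk_count,
       prevalence_pct = summ$prevalence_pct)

  # stage 3: reducer comparison
  feats <- cohort_features(scored)
  cmp <- compare_reducers(feats$X, feats$labels, k = cfg$k,
                          gpca_seed = child_seed(cfg$seed, "gpca"))
  utils::write.csv(cmp$table, file.path(cfg$out_dir, "variance_comparison.csv"),
                   row.names = FALSE)
  emit("variance_comparison.csv")
  ccpca <- cmp$models$CCPCA
  utils::write.csv(eigenvalue_table(ccpca),
                   file.path(cfg$out_dir, "eigenvalue_table.csv"),
                   row.names = FALSE)
  emit("eigenvalue_table.csv")
  ranking <- rank_discriminant_power(ccpca)
  utils::write.csv(ranking, file.path(cfg$out_dir, "discriminant_ranking.csv"),
                   row.names = FALSE)
  emit("discriminant_ranking.csv")
  fa <- assign_features(ccpca, threshold = cfg$loading_threshold)
  selected <- fa$selected
  fallback_used <- FALSE
  if (length(selected) < 2) {
    # threshold too strict for this run: fall back to the top-ranked features
    selected <- utils::head(ranking$feature, 4)
    fallback_used <- TRUE
    manifest$warnings <- c(manifest$warnings, sprintf(
      "loading threshold %.2f selected %d feature(s); fell back to top-4 discriminant ranking",
      cfg$loading_threshold, length(fa$selected)))
  }
  note("reducers", k = cfg$k, variance_pct = cmp$table$pct_variance_explained,
       selected_features = selected, fallback_used = fallback_used,
       reconstruction_note = "CCPCA centroid-span and LDA Fisher-hybrid are reconstructions of conceptually described methods")

  # stage 4: classifier benchmark
  bench_cfg <- cfg$bench
  bench_cfg$seed <- child_seed(cfg$seed, "bench")
  grid <- run_grid(feats$X, feats$labels, cfg = bench_cfg)
  utils::write.csv(grid_table(grid), file.path(cfg$out_dir, "accuracy_grid.csv"),
                   row.names = FALSE)
  emit("accuracy_grid.csv")
  best <- select_best(grid)
  note("bench", scheme = grid$scheme, best_classifier = best$classifier,
       best_components = best$components, best_accuracy = best$accuracy)

  # stage 5: risk tree on the selected raw features
  tree_cfg <- cfg$tree
  tree_cfg$features <- selected
  tree <- fit_risk_tree(as.data.frame(feats$X), feats$labels, tree_cfg)
  cons <- check_conservation(tree)
  if (!cons$pass) abort_sf12("risk tree failed conservation check")
  tree_to_json(tree, file.path(cfg$out_dir, "risk_tree.json"))
  emit("risk_tree.json")
  writeLines(render_tree(tree, "dot"), file.path(cfg$out_dir, "risk_tree.dot"))
  emit("risk_tree.dot")
  path_rep <- path_risk_report(tree)
  utils::write.csv(path_rep, file.path(cfg$out_dir, "risk_tree_paths.csv"),
                   row.names = FALSE)
  emit("risk_tree_paths.csv")
  note("tree", features = selected, n_nodes = nrow(path_rep),
       root_risk_pct = path_rep$risk_pct[1],
       conservation = cons$pass)

  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest()
  invisible(list(scored = scored, summary = summ, comparison = cmp,
                 assignment = fa, selected = selected, grid = grid,
                 best = best, tree = tree, path_report = path_rep,
                 manifest = manifest, out_dir = cfg$out_dir))
}

#' Human-readable run report
#'
#' Juxtaposes the numbers a pipeline run produced with the published
#' reference targets the generator emulates, clearly labelling which is
#' which. Missing artifacts are listed as absent; the report is still
#' produced.
#'
#' @param run the list returned by [run_pipeline()], or an `out_dir` path.
#' @return character vector of report lines (also printable with `cat`).
#' @export
make_report <- function(run) {
  if (is.character(run)) {
    out_dir <- run
    manifest <- jsonlite::fromJSON(file.path(out_dir, "manifest.json"),
                                   simplifyVector = TRUE)
    ref <- reference_targets()
    lines <- c("SF-12 depression-risk pipeline report",
               sprintf("run directory: %s", out_dir))
    s <- manifest$stages
    if (!is.null(s$scoring)) {
      lines <- c(lines, sprintf(
        "prevalence (this run, emulation): %.2f%% [n=%d] | published reference: %.2f%%",
        s$scoring$prevalence_pct, s$scoring$n, 100 * ref$prevalence))
    }
    if (!is.null(s$bench)) {
      lines <- c(lines, sprintf(
        "best classifier (this run): %s with %d component(s), accuracy %.3f [%s]",
        s$bench$best_classifier, s$bench$best_components,
        s$bench$best_accuracy, s$bench$scheme))
    }
    if (!is.null(s$tree)) {
      lines <- c(lines, sprintf(
        "risk tree: %d nodes on {%s}; a-priori risk %.2f%%",
        s$tree$n_nodes, paste(unlist(s$tree$features), collapse = ", "),
        s$tree$root_risk_pct))
    }
    expected <- c("scored_cohort.csv", "domain_summary.csv",
                  "variance_comparison.csv", "eigenvalue_table.csv",
                  "discriminant_ranking.csv", "accuracy_grid.csv",
                  "risk_tree.json", "risk_tree.dot", "risk_tree_paths.csv")
    absent <- expected[!file.exists(file.path(out_dir, expected))]
    if (length(absent) > 0) {
      lines <- c(lines, sprintf("ABSENT artifact(s): %s",
                                paste(absent, collapse = ", ")))
    }
    if (length(manifest$warnings) > 0) {
      lines <- c(lines, paste("warning:", manifest$warnings))
    }
    return(lines)
  }
  make_report(run$out_dir)
}
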