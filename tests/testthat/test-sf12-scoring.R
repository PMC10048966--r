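# SF-12 scoring: validation, domain scores, component summaries, risk label

test_that("validate_responses accepts valid codes and rejects bad records", {
  expect_s3_class(validate_responses(uniform_responses(code = 1)), "sf12_responses")
  bad <- uniform_responses()
  bad$sf12_q1 <- 99
  expect_error(validate_responses(bad), "sf12_q1.*1\\.\\.5",
               class = "sf12risk_validation_error")
  expect_error(validate_responses(uniform_responses()[-1]), "sf12_q1",
               class = "sf12risk_validation_error")
  miss <- uniform_responses()
  miss$sf12_q5 <- NA
  expect_error(validate_responses(miss), "sf12_q5",
               class = "sf12risk_validation_error")
  expect_s3_class(validate_responses(miss, impute = "halfscale"), "sf12_responses")
})

test_that("half-scale imputation fills with the respondent's domain mean", {
  # 3-item toy domain: engine is generic over the item map
  toy_map <- data.frame(item = c("q1", "q2", "q3"), domain = "TOY",
                        levels = 5L, reverse = FALSE)
  raw <- data.frame(q1 = 2, q2 = 4, q3 = NA)
  resp <- validate_responses(raw, item_map = toy_map, impute = "halfscale")
  dom <- score_domains(resp)
  # hand-computed: items recode to 25 and 75; mean of answered = 50
  expect_equal(dom$TOY, 50)
  # fewer than half answered -> reject
  raw2 <- data.frame(q1 = 2, q2 = NA, q3 = NA)
  expect_error(score_domains(validate_responses(raw2, item_map = toy_map,
                                                impute = "halfscale")),
               "fewer than half", class = "sf12risk_validation_error")
})

test_that("domain scores hit the scale anchors and midpoint", {
  expect_true(all(score_domains(validate_responses(best_health_responses())) == 100))
  expect_true(all(score_domains(validate_responses(worst_health_responses())) == 0))
  # PF is a 2-item domain: one best + one worst response -> 50 by linearity
  mid <- best_health_responses()
  mid$sf12_q2 <- 1L   # worst on a non-reversed 3-level item
  expect_equal(score_domains(validate_responses(mid))$PF, 50)
})

test_that("domain scores are bounded and monotone in single-item improvements", {
  imap <- sf12_item_map()
  for (d in unique(imap$domain)) {
    sub <- imap[imap$domain == d, ]
    combos <- expand.grid(lapply(sub$levels, seq_len))
    names(combos) <- sub$item
    # exhaustive enumeration of the domain's response space
    full <- uniform_responses(nrow(combos))
    full[names(combos)] <- combos
    sc <- score_domains(validate_responses(full))[[d]]
    expect_true(all(sc >= 0 & sc <= 100))
    # improving one item (toward better health) never decreases the score
    for (i in seq_len(nrow(sub))) {
      dir <- if (sub$reverse[i]) -1L else 1L
      # step one code toward better health where possible
      can_step <- if (dir == 1L) combos[[i]] < sub$levels[i] else combos[[i]] > 1L
      stepped <- combos
      stepped[[i]] <- stepped[[i]] + ifelse(can_step, dir, 0L)
      full2 <- uniform_responses(nrow(stepped))
      full2[names(stepped)] <- stepped
      sc2 <- score_domains(validate_responses(full2))[[d]]
      expect_true(all(sc2 >= sc))
    }
  }
})

test_that("component summaries follow the norm-based closed form", {
  coef <- default_scoring_coefficients()
  # domains exactly at the normalization means -> both T-scores are 50
  at_mean <- as.data.frame(as.list(stats::setNames(coef$norm_mean, coef$domain)))
  cs <- score_components(at_mean, coef)
  expect_equal(cs$PCS, 50)
  expect_equal(cs$MCS, 50)
  # identity coefficients: one-hot MH weight, unit SDs, zero means
  ident <- coef
  ident$norm_mean <- 0
  ident$norm_sd <- 1
  ident$mcs_weight <- as.numeric(ident$domain == "MH")
  dom <- as.data.frame(as.list(stats::setNames(c(10, 20, 30, 40, 50, 60, 70, 35),
                                               sf12_domains())))
  expect_equal(score_components(dom, ident)$MCS, 10 * dom$MH + 50)
  # random domain vector vs independent spreadsheet-style recomputation
  set.seed(42)
  dom2 <- as.data.frame(as.list(stats::setNames(runif(8, 0, 100), sf12_domains())))
  got <- score_components(dom2, coef)
  exp_pcs <- 50; exp_mcs <- 50
  for (j in seq_len(8)) {
    z <- (dom2[[coef$domain[j]]] - coef$norm_mean[j]) / coef$norm_sd[j]
    exp_pcs <- exp_pcs + 10 * coef$pcs_weight[j] * z
    exp_mcs <- exp_mcs + 10 * coef$mcs_weight[j] * z
  }
  expect_equal(got$PCS, exp_pcs, tolerance = 1e-10)
  expect_equal(got$MCS, exp_mcs, tolerance = 1e-10)
  # wrong arity -> configuration error
  expect_error(score_components(dom2, coef[-1, ]),
               class = "sf12risk_config_error")
})

test_that("depression-risk flag applies the strict MCS < 42 rule", {
  expect_identical(flag_depression_risk(data.frame(MCS = 41.99)), 1L)
  expect_identical(flag_depression_risk(data.frame(MCS = 42.00)), 0L)
  expect_identical(flag_depression_risk(data.frame(MCS = 47.87)), 0L)
  expect_error(flag_depression_risk(data.frame(MCS = NaN)), "non-finite")
  # threshold coherence: non-increasing step function of MCS
  mcs <- sort(runif(200, 20, 70))
  flags <- flag_depression_risk(mcs)
  expect_true(all(diff(flags) <= 0))
})

test_that("summarize_cohort reports prevalence to two decimals and exactly", {
  cal <- calibrated_cfg()
  co <- generate_cohort(cal, seed = 10)
  s <- summarize_cohort(co)
  expect_equal(s$prevalence_pct, round(100 * s$risk_count / s$n, 2))
  expect_identical(s$risk_count, sum(co$depression_risk))
  # 63 flagged of 217
  fake <- co
  fake$depression_risk <- c(rep(1L, 63), rep(0L, 154))
  expect_equal(summarize_cohort(fake)$prevalence_pct, 29.03)
  fake$depression_risk <- 0L
  expect_equal(summarize_cohort(fake)$prevalence_pct, 0)
  # single patient: mean is the value, SD reported as 0
  one <- fake[1, ]
  one$VT <- 80
  s1 <- summarize_cohort(one)
  expect_equal(s1$table$mean[s1$table$variable == "VT"], 80)
  expect_equal(s1$table$sd[s1$table$variable == "VT"], 0)
  expect_error(summarize_cohort(fake[0, ]), "empty")
})

test_that("coefficient tables round-trip through CSV", {
  coef <- default_scoring_coefficients()
  path <- withr::local_tempfile(fileext = ".csv")
  write_scoring_coefficients(coef, path)
  back <- read_scoring_coefficients(path)
  expect_equal(as.data.frame(back), as.data.frame(coef))
  bad <- coef
  bad$norm_sd[3] <- 0
  expect_error(validate_scoring_coefficients(bad), "positive",
               class = "sf12risk_config_error")
})
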