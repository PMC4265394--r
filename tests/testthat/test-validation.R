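# Calibration, goodness of fit, ROC/AUC, and the DeLong comparison.

test_that("horizon outcomes follow the endpoint rule table", {
  co <- make_cohort(
    make_record(id = "e1", outcome = "bc_death", follow_up_years = 4.2),
    make_record(id = "e2", outcome = "bc_death", follow_up_years = 10),
    make_record(id = "n1", outcome = "censored", follow_up_years = 12),
    make_record(id = "n2", outcome = "bc_death", follow_up_years = 11.5),
    make_record(id = "n3", outcome = "other_death", follow_up_years = 10.5),
    make_record(id = "c1", outcome = "censored", follow_up_years = 6),
    make_record(id = "d1", outcome = "other_death", follow_up_years = 3)
  )
  obs <- observed_outcomes(co, horizon = 10)
  expect_equal(as.character(obs),
               c("event", "event", "non_event", "non_event", "non_event",
                 "censored", "competing_death"))
  co$records$follow_up_years[1] <- -1
  expect_error(observed_outcomes(co), "non-negative")
})

test_that("calibration sums predictions within strata and is additive over partitions", {
  co <- make_cohort(
    make_record(id = "a", outcome = "bc_death", follow_up_years = 2),
    make_record(id = "b"), make_record(id = "c"), make_record(id = "d")
  )
  pred <- data.frame(id = c("a", "b", "c", "d"),
                     cuminc_bc_10 = c(0.1, 0.2, 0.3, 0.4))
  one <- calibration_table(co, pred, pred, rep("all", 4))
  expect_equal(one$expected_v2, 1.0)
  expect_equal(one$observed_deaths, 1)
  expect_true(one$ci_low < 1 && one$ci_high > 1)

  split2 <- calibration_table(co, pred, pred, c("g1", "g1", "g2", "g2"))
  expect_equal(sum(split2$expected_v2), one$expected_v2)
  expect_equal(sum(split2$observed_deaths), one$observed_deaths)
  expect_equal(split2$expected_v2, c(0.3, 0.7))

  zero <- data.frame(id = pred$id, cuminc_bc_10 = 0)
  expect_equal(calibration_table(co, zero, zero, c("g1", "g1", "g2", "g2"))$expected_v2,
               c(0, 0))

  expect_error(calibration_table(co, pred, pred, c("g1", NA, "g2", "g2")), "strata")
  expect_error(calibration_table(co, pred[1:3, ], pred, rep("all", 4)), "missing")
})

test_that("exact Poisson intervals cover the observed count sensibly", {
  tab <- calibration_table(
    make_cohort(make_record(id = "a")),
    data.frame(id = "a", cuminc_bc_10 = 0.5),
    data.frame(id = "a", cuminc_bc_10 = 0.5),
    "all")
  expect_equal(tab$ci_low, 0)
  expect_gt(tab$ci_high, 3)  # exact upper bound for zero observed events
})

test_that("chi-squared goodness of fit matches hand arithmetic and its invariances", {
  expect_equal(gof_chi2(c(2, 3), c(1, 4), df = 2)$chi2, 1 / 1 + 1 / 4)
  perfect <- gof_chi2(c(5, 5, 5), c(5, 5, 5), df = 3)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  # doubling O and E doubles the statistic
  expect_equal(gof_chi2(c(4, 6), c(2, 8), df = 2)$chi2,
               2 * gof_chi2(c(2, 3), c(1, 4), df = 2)$chi2)
  # invariant under bin relabelling
  expect_equal(gof_chi2(c(3, 2), c(4, 1), df = 2)$chi2,
               gof_chi2(c(2, 3), c(1, 4), df = 2)$chi2)
  expect_error(gof_chi2(c(1, 0), c(0, 2), df = 2), "zero expected")
  expect_equal(gof_chi2(c(0, 2), c(0, 2), df = 2)$chi2, 0)
})

test_that("quantile binning is stable under ties and feeds the GOF test", {
  co <- impute_missing(simulate_cohort(simulation_spec(n = 200, seed = 31)))
  pred <- predict_cohort(co, default_model_config(), "v3")
  q <- strata_quantile(pred, 5)
  expect_equal(as.vector(table(q)), rep(40, 5))
  expect_identical(q, strata_quantile(pred, 5))
  # bins are ordered in predicted risk
  means <- tapply(pred$cuminc_bc_10, q, mean)
  expect_true(all(diff(means) > 0))
  g <- quantile_gof(co, pred, k = 5)
  expect_equal(g$df, 5)
  expect_gte(g$chi2, 0)
  expect_true(g$p >= 0 && g$p <= 1)
  expect_error(strata_quantile(pred, 1), "k")
})

test_that("AUC handles perfect separation, total ties, and the 2x2 enumeration", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  ties <- roc_auc(rep(0.4, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(ties$auc, 0.5)
  # events {0.9, 0.4}, non-events {0.5, 0.1}: 3 of 4 pairs concordant
  two <- roc_auc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(two$auc, 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "non-event")
})

test_that("AUC equals exhaustive pairwise enumeration and ignores monotone rescaling", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    event <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- if (i %% 3 == 0) sample(0:9, n, TRUE) / 10 else rnorm(n)
    r <- roc_auc(scores, event)
    expect_equal(r$auc, auc_by_enumeration(scores, event), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC unchanged
    r2 <- roc_auc(qlogis((rank(scores, ties.method = "average")) / (n + 1)), event)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("ROC curve is a monotone path from (0,0) to (1,1)", {
  set.seed(5)
  r <- roc_auc(round(rnorm(60), 1), runif(60) < 0.3)
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("DeLong AUC variance agrees with pROC on a fixed instance", {
  skip_if_not_installed("pROC")
  set.seed(33)
  n <- 120
  event <- runif(n) < 0.35
  sa <- rnorm(n) + event
  sb <- 0.8 * sa + rnorm(n, sd = 0.7)
  r <- roc_auc(sa, event)
  pr <- pROC::roc(response = event, predictor = sa, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$variance, as.numeric(pROC::var(pr, method = "delong")),
               tolerance = 1e-12)
  dl <- delong_test(sa, sb, event)
  pt <- pROC::roc.test(pROC::roc(event, sa, quiet = TRUE, direction = "<"),
                       pROC::roc(event, sb, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(abs(dl$z), abs(as.numeric(pt$statistic)), tolerance = 1e-10)
  expect_equal(dl$p, as.numeric(pt$p.value), tolerance = 1e-10)
})

test_that("DeLong comparison is antisymmetric and degenerates gracefully", {
  set.seed(44)
  event <- runif(40) < 0.4
  sa <- rnorm(40) + event
  sb <- rnorm(40) + 0.5 * event
  ab <- delong_test(sa, sb, event)
  ba <- delong_test(sb, sa, event)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-15)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_true(ab$var_delta >= 0)

  expect_warning(self <- delong_test(sa, sa, event), "degenerate")
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
})

test_that("DeLong z agrees with a stratified paired bootstrap on a small printed fixture", {
  # n = 8 patients, two correlated scores
  event <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  sa <- c(0.81, 0.62, 0.55, 0.67, 0.41, 0.38, 0.22, 0.15)
  sb <- c(0.85, 0.58, 0.69, 0.55, 0.47, 0.30, 0.28, 0.11)
  dl <- delong_test(sa, sb, event)
  z_boot <- bootstrap_delong_z(sa, sb, event, n_boot = 10000, seed = 404)
  expect_lt(abs(dl$z - z_boot), 0.1)
})

test_that("delta AUC interval covers zero at the nominal rate under exchangeable noise", {
  set.seed(505)
  hits <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    event <- rep(c(TRUE, FALSE), c(30, 70))
    base <- rnorm(100) + event
    sa <- base + rnorm(100, sd = 0.5)
    sb <- base + rnorm(100, sd = 0.5)
    dl <- delong_test(sa, sb, event)
    ci <- dl$delta + c(-1.96, 1.96) * sqrt(dl$var_delta)
    if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.995)
})
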