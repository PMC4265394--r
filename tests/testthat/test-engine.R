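# Prediction engine: marker renormalization, relative hazards, competing
# risks curves, and treatment benefits.

test_that("marker renormalization reproduces the published KI67 relative hazards", {
  m <- renormalize_marker(1.3, 0.412)
  expect_equal(round(m$h_neg, 2), 0.89)
  expect_equal(round(m$h_pos, 2), 1.16)
  expect_equal(m$h_pos / m$h_neg, 1.3, tolerance = 1e-12)
  expect_equal(0.412 * m$h_pos + (1 - 0.412) * m$h_neg, 1, tolerance = 1e-12)
})

test_that("renormalization solves the two constraints exactly across the HR range", {
  expect_equal(renormalize_marker(1, 0.3), list(h_neg = 1, h_pos = 1))
  expect_equal(renormalize_marker(2, 0.5), list(h_neg = 2 / 3, h_pos = 4 / 3))
  set.seed(7)
  for (i in 1:200) {
    hr <- runif(1, 0.1, 10)
    p <- runif(1, 0.01, 0.99)
    m <- renormalize_marker(hr, p)
    expect_equal(p * m$h_pos + (1 - p) * m$h_neg, 1, tolerance = 1e-12)
    expect_equal(m$h_pos / m$h_neg, hr, tolerance = 1e-12)
  }
  expect_error(renormalize_marker(1.3, 0), "prevalence")
  expect_error(renormalize_marker(1.3, 1), "prevalence")
  expect_error(renormalize_marker(-1, 0.5), "hr")
})

test_that("relative hazard multiplies published per-unit hazard ratios", {
  cfg <- default_model_config()
  # ER-, all baseline categories, screen detected, markers neutral
  r <- make_record(er = "neg", detection = "screen")
  expect_equal(relative_hazard(r, cfg, "v2"), 0.86, tolerance = 1e-12)
  # ER+, baseline, symptomatic: empty product
  expect_equal(relative_hazard(make_record(), cfg, "v2"), 1, tolerance = 1e-12)
  # ER+: nodes 3 (code 2), 15 mm (code 1), grade high (code 2)
  r3 <- make_record(nodes_pos = 3, size_mm = 15, grade = 2)
  expect_equal(relative_hazard(r3, cfg, "v2"), 1.75^2 * 1.43 * 2.33^2,
               tolerance = 1e-3)
  expect_equal(relative_hazard(r3, cfg, "v2"), 23.775, tolerance = 1e-3)
})

test_that("relative hazard is strictly increasing in each category code", {
  cfg <- default_model_config()
  base <- relative_hazard(make_record(), cfg, "v3")
  for (node in 1:4) {
    stepped <- relative_hazard(make_record(nodes_pos = c(1, 2, 5, 10)[node]), cfg, "v3")
    expect_gt(stepped, base)
  }
  sizes <- c(5, 15, 25, 40, 60)
  rh_size <- sapply(sizes, function(s) relative_hazard(make_record(size_mm = s), cfg, "v3"))
  expect_true(all(diff(rh_size) > 0))
  rh_grade <- sapply(0:2, function(g) relative_hazard(make_record(grade = g), cfg, "v3"))
  expect_true(all(diff(rh_grade) > 0))
})

test_that("KI67 enters only in v3 for ER-positive disease", {
  cfg <- default_model_config()
  pos_k <- make_record(ki67 = 1)
  expect_equal(relative_hazard(pos_k, cfg, "v2"), 1)
  m <- renormalize_marker(cfg$ki67$hr, cfg$ki67$prevalence)
  expect_equal(relative_hazard(pos_k, cfg, "v3"), m$h_pos, tolerance = 1e-12)
  expect_equal(relative_hazard(make_record(ki67 = 0), cfg, "v3"), m$h_neg,
               tolerance = 1e-12)
  # ER-negative: KI67 ignored entirely
  neg <- make_record(er = "neg", ki67 = 1)
  expect_equal(relative_hazard(neg, cfg, "v3"),
               relative_hazard(neg, cfg, "v2"), tolerance = 1e-15)
  # fractional status at the configured prevalence: mean-one transfers,
  # so v3 equals v2
  frac <- make_record(ki67 = cfg$ki67$prevalence, nodes_pos = 2, grade = 1)
  expect_equal(relative_hazard(frac, cfg, "v3"),
               relative_hazard(frac, cfg, "v2"), tolerance = 1e-12)
})

test_that("uncoded or impossible records are rejected", {
  cfg <- default_model_config()
  expect_error(relative_hazard(make_record(size_mm = NA), cfg, "v2"), "coded")
  expect_error(relative_hazard(make_record(her2 = NA), cfg, "v2"), "coded")
  rec <- make_record()
  rec$er <- "unknown"
  expect_error(relative_hazard(rec, cfg, "v2"), "ER")
  rec2 <- make_record(grade = NA)
  rec2$grade <- -1
  expect_error(relative_hazard(rec2, cfg, "v2"), "negative")
})

test_that("null hazards give flat survival and zero cumulative incidence", {
  cfg <- flat_config(bc = 0, oc = 0)
  cv <- survival_curves(make_record(), cfg, "v2")
  expect_equal(unname(cv$s_bc), rep(1, 11))
  expect_equal(unname(cv$s_oc), rep(1, 11))
  expect_equal(unname(cv$cuminc_bc), rep(0, 11))
  expect_equal(unname(cv$cuminc_oc), rep(0, 11))
})

test_that("survival matches the closed form for constant hazard and no competing risk", {
  # lambda = 0.02/yr, relative hazard 2 (node code 1 with hr_node = 2)
  cfg <- flat_config(bc = 0.02, oc = 0, hr_node = 2)
  cv <- survival_curves(make_record(nodes_pos = 1), cfg, "v2")
  expect_equal(unname(cv$s_bc[11]), exp(-0.4), tolerance = 1e-9)
  expect_equal(unname(cv$s_bc), exp(-0.04 * 0:10), tolerance = 1e-9)
  expect_equal(unname(cv$cuminc_bc[11]), 1 - exp(-0.4), tolerance = 1e-9)
  expect_equal(unname(cv$cuminc_oc), rep(0, 11))
})

test_that("equal cause-specific hazards split mortality equally", {
  cfg <- flat_config(bc = 0.03, oc = 0.03)
  cv <- survival_curves(make_record(), cfg, "v2")
  expect_equal(cv$cuminc_bc, cv$cuminc_oc, tolerance = 1e-12)
})

test_that("curves are monotone and conserve total probability", {
  cfg <- default_model_config()
  set.seed(21)
  co <- impute_missing(simulate_cohort(simulation_spec(n = 150, seed = 21)))
  for (v in c("v2", "v3")) {
    pred <- predict_cohort(co, cfg, v)
    cv <- attr(pred, "curves")
    expect_true(all(diff(t(cv$s_bc)) <= 1e-15))
    expect_true(all(diff(t(cv$s_oc)) <= 1e-15))
    expect_true(all(cv$s_bc >= 0 & cv$s_bc <= 1))
    expect_equal(unname(cv$s_bc[, 1]), rep(1, n_patients(co)))
    total <- cv$s_bc * cv$s_oc + cv$cuminc_bc + cv$cuminc_oc
    expect_true(all(abs(total - 1) < 1e-9))
  }
})

test_that("treatment benefit behaves as the hazard multipliers dictate", {
  # identity multiplier: benefit exactly zero
  cfg1 <- flat_config(bc = 0.02, treatment = list(endocrine = 1, chemo = 1))
  b <- treatment_benefit(make_record(nodes_pos = 2), cfg1, "v2")
  expect_equal(b$benefit_5, rep(0, 3))
  expect_equal(b$benefit_10, rep(0, 3))

  # protective multiplier on a positive hazard: positive benefit,
  # combined therapy at least as large as either alone
  cfg <- flat_config(bc = 0.02, oc = 0.01)
  b2 <- treatment_benefit(make_record(nodes_pos = 2, grade = 2), cfg, "v2")
  expect_true(all(b2$benefit_10 > 0))
  expect_gt(b2$benefit_10[b2$therapy == "both"],
            max(b2$benefit_10[b2$therapy != "both"]))

  # no breast-cancer hazard: nothing to prevent
  cfg0 <- flat_config(bc = 0, oc = 0.01)
  b0 <- treatment_benefit(make_record(), cfg0, "v2")
  expect_equal(b0$benefit_10, rep(0, 3))

  expect_error(flat_config(treatment = list(endocrine = -0.5, chemo = 0.8)),
               "treatment")
})

test_that("cohort prediction is deterministic, aligned, and v2 = v3 on ER-negative records", {
  cfg <- default_model_config()
  co <- impute_missing(simulate_cohort(simulation_spec(n = 120, seed = 8)))
  p2 <- predict_cohort(co, cfg, "v2")
  p3 <- predict_cohort(co, cfg, "v3")
  expect_equal(p2$id, co$records$id)
  neg <- co$records$er == "neg"
  expect_equal(p2$cuminc_bc_10[neg], p3$cuminc_bc_10[neg], tolerance = 1e-15)
  expect_equal(p2$s_bc_10[neg], p3$s_bc_10[neg], tolerance = 1e-15)
  expect_false(isTRUE(all.equal(p2$cuminc_bc_10[!neg], p3$cuminc_bc_10[!neg])))
  # determinism and duplicated-record equality
  expect_equal(predict_cohort(co, cfg, "v2"), p2)
  rec <- co$records[c(1, 1), ]
  rec$id <- c("d1", "d2")
  pd <- predict_cohort(new_cohort(rec), cfg, "v3")
  expect_equal(pd$cuminc_bc_10[1], pd$cuminc_bc_10[2])
  # empty cohort
  expect_equal(nrow(predict_cohort(new_cohort(co$records[0, ]), cfg, "v2")), 0)
})

test_that("horizon cannot exceed the configured baseline arrays", {
  cfg <- flat_config(H = 5)
  cfg$horizon_years <- 8
  expect_error(validate_model_config(cfg), "horizon")
})
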