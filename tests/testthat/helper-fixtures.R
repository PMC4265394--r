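# Shared fixtures: records, simplified configs, and independent oracles
# (exhaustive pairwise AUC; stratified paired bootstrap for the AUC
# difference) used to cross-check the implementation.

# A single fully coded record. Markers default to their configured
# prevalences, i.e. a "neutral" status whose mean-one term is exactly 1.
make_record <- function(id = "r1", age_dx = 55, size_mm = 5, grade = 0,
                        nodes_pos = 0, nodes_sampled = 10, er = "pos",
                        her2 = 0.089, ki67 = 0.412,
                        detection = "symptomatic", therapy = "none",
                        follow_up_years = 10, outcome = "censored") {
  data.frame(id = id, age_dx = age_dx, size_mm = size_mm, grade = grade,
             nodes_pos = nodes_pos, nodes_sampled = nodes_sampled, er = er,
             her2 = her2, ki67 = ki67, detection = detection,
             therapy = therapy, follow_up_years = follow_up_years,
             outcome = outcome, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  new_cohort(do.call(rbind, rows))
}

# Config with constant annual hazards so survival is closed-form
# exponential: s_bc(t) = exp(-bc * RH * t) when oc = 0.
flat_config <- function(bc = 0.02, oc = 0, H = 10,
                        hr_node = 2, hr_size = 1.5, hr_grade = 1.5,
                        hr_screen = 0.8, treatment = list(endocrine = 0.7, chemo = 0.78)) {
  stratum <- list(hr_node = hr_node, hr_size = hr_size, hr_grade = hr_grade,
                  hr_screen = hr_screen,
                  baseline_annual_hazard = rep(bc, H))
  validate_model_config(list(
    er_pos = stratum, er_neg = stratum,
    ki67 = list(hr = 1.3, prevalence = 0.412),
    her2 = list(hr = 1.8, prevalence = 0.089),
    life_table = list(age = c(0, 120), annual_hazard = rep(oc, 2)),
    treatment = treatment,
    horizon_years = H
  ))
}

# Independent AUC oracle: exhaustive enumeration of all (event, non-event)
# pairs with the tie kernel 1/2.
auc_by_enumeration <- function(scores, event) {
  xs <- scores[event]
  ys <- scores[!event]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Paired bootstrap oracle for the DeLong z statistic: resample patients
# within outcome classes (keeping both classes non-empty), recompute the
# AUC difference, and studentize the observed difference by the bootstrap
# standard deviation.
bootstrap_delong_z <- function(scores_a, scores_b, event, n_boot = 10000, seed = 202) {
  set.seed(seed)
  idx_pos <- which(event)
  idx_neg <- which(!event)
  obs <- auc_by_enumeration(scores_b, event) - auc_by_enumeration(scores_a, event)
  deltas <- replicate(n_boot, {
    i <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
           sample(idx_neg, length(idx_neg), replace = TRUE))
    e <- event[i]
    auc_by_enumeration(scores_b[i], e) - auc_by_enumeration(scores_a[i], e)
  })
  obs / stats::sd(deltas)
}

# Fixture replicating the published staging-exclusion arithmetic: 2,232
# records of which 506 are node negative with fewer than four nodes
# sampled; 1,274 of the 1,726 adequately staged records are ER positive.
staging_fixture_cohort <- function() {
  set.seed(99)
  n <- 2232
  n_excl <- 506
  n_keep <- n - n_excl
  n_erpos <- 1274
  rec <- make_record(id = "x")[rep(1, n), ]
  rec$id <- sprintf("N%04d", seq_len(n))
  excl <- seq_len(n_excl)
  rec$nodes_pos[excl] <- 0
  rec$nodes_sampled[excl] <- sample(0:3, n_excl, replace = TRUE)
  keep <- (n_excl + 1):n
  rec$nodes_pos[keep] <- sample(0:12, n_keep, replace = TRUE)
  rec$nodes_sampled[keep] <- pmax(rec$nodes_pos[keep], 4) + sample(0:10, n_keep, replace = TRUE)
  rec$er <- "neg"
  rec$er[keep[seq_len(n_erpos)]] <- "pos"
  new_cohort(rec)
}
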