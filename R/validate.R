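# Calibration machinery: horizon-restricted outcome classification,
# observed-vs-expected death counts by strata or risk quantiles with exact
# Poisson intervals, and the chi-squared goodness-of-fit over quantile bins.

#' Classify each patient's outcome at a horizon
#'
#' The endpoint is breast-cancer-specific mortality at a fixed horizon
#' (default 10 years). A breast-cancer death at or before the horizon is an
#' `event`; surviving past the horizon (alive, censored at or beyond it, or
#' dying of any cause after it) is a `non_event`; deaths from other causes
#' before the horizon and censoring before the horizon are flagged
#' distinctly so downstream censoring policies can treat them differently.
#'
#' @param cohort an `ebc_cohort`.
#' @param horizon years (default 10).
#' @return Factor with levels `event`, `non_event`, `competing_death`,
#'   `censored`.
#' @export
observed_outcomes <- function(cohort, horizon = 10) {
  rec <- as_record_df(cohort)
  fu <- rec$follow_up_years
  if (any(is.na(fu)) || any(fu < 0)) stop("follow_up_years must be non-negative")
  out <- rep("non_event", nrow(rec))
  out[rec$outcome == "bc_death" & fu <= horizon] <- "event"
  out[rec$outcome == "other_death" & fu < horizon] <- "competing_death"
  out[rec$outcome == "censored" & fu < horizon] <- "censored"
  factor(out, levels = c("event", "non_event", "competing_death", "censored"))
}

# Exact (Poisson) 95% interval for an observed event count.
poisson_ci <- function(count, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(count == 0, 0, stats::qchisq(a, 2 * count) / 2)
  hi <- stats::qchisq(1 - a, 2 * (count + 1)) / 2
  cbind(lo = lo, hi = hi)
}

#' Observed vs expected breast-cancer deaths by stratum
#'
#' For each stratum, counts observed breast-cancer deaths within the horizon
#' and sums each model's predicted cumulative breast-cancer mortality at the
#' horizon (the expected count). Exact Poisson 95% intervals accompany the
#' observed counts.
#'
#' @param cohort an imputed `ebc_cohort`.
#' @param predictions_v2,predictions_v3 `ebc_predictions` aligned to the
#'   cohort by `id` (pass the same object twice to tabulate one model).
#' @param strata factor (or character vector) of stratum labels, one per
#'   patient with no `NA`, e.g. from [strata_table_groups()] or
#'   [strata_quantile()].
#' @param horizon years (default 10).
#' @return data.frame with `label`, `n`, `observed_deaths`, `expected_v2`,
#'   `expected_v3`, `ci_low`, `ci_high`.
#' @export
calibration_table <- function(cohort, predictions_v2, predictions_v3, strata,
                              horizon = 10) {
  rec <- as_record_df(cohort)
  strata <- as.factor(strata)
  if (length(strata) != nrow(rec) || anyNA(strata)) {
    stop("strata must label every patient exactly once (no NA)")
  }
  align <- function(pred) {
    idx <- match(rec$id, pred$id)
    if (anyNA(idx)) stop("predictions are missing cohort ids")
    pred$cuminc_bc_10[idx]
  }
  e2 <- align(predictions_v2)
  e3 <- align(predictions_v3)
  obs <- observed_outcomes(cohort, horizon) == "event"
  labs <- levels(strata)
  n <- as.vector(table(strata))
  observed <- as.vector(tapply(obs, strata, sum, default = 0))
  ci <- poisson_ci(observed)
  data.frame(
    label = labs,
    n = n,
    observed_deaths = observed,
    expected_v2 = as.vector(tapply(e2, strata, sum, default = 0)),
    expected_v3 = as.vector(tapply(e3, strata, sum, default = 0)),
    ci_low = unname(ci[, "lo"]),
    ci_high = unname(ci[, "hi"]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Clinical calibration strata
#'
#' Builds the standard clinical strata used for calibration tables: age
#' bands (<40, 40-49, 50-59, 60+), size bands (<10, 10-19, 20-29, 30-49,
#' 50+ mm), node-status bands (negative, 1, 2-4, 5-9, 10+), grade, and HER2
#' status, each with a `Missing` level when the cohort carries pre-imputation
#' missingness flags.
#'
#' @param cohort an `ebc_cohort` (imputed cohorts retain `*_missing` flags).
#' @return Named list of factors, each a partition of the cohort.
#' @export
strata_table_groups <- function(cohort) {
  rec <- as_record_df(cohort)
  miss <- function(flag) {
    if (!is.null(rec[[flag]])) rec[[flag]] else rep(FALSE, nrow(rec))
  }
  with_missing <- function(x, flag, levels) {
    x <- as.character(x)
    x[miss(flag)] <- "Missing"
    factor(x, levels = c(levels, if (any(x == "Missing")) "Missing"))
  }
  age_lab <- c("<40", "40-49", "50-59", "60+")
  age <- age_lab[findInterval(rec$age_dx, c(0, 40, 50, 60))]
  size_lab <- c("<10", "10-19", "20-29", "30-49", "50+")
  size <- size_lab[size_code(rec$size_mm) + 1]
  node_lab <- c("Negative", "1", "2-4", "5-9", "10+")
  ncode <- if (!is.null(rec$node_code)) rec$node_code else node_code(rec$nodes_pos)
  node <- node_lab[pmin(floor(ncode), 4) + 1]
  grade_lab <- c("1", "2", "3")
  grade <- grade_lab[pmin(floor(rec$grade), 2) + 1]
  her2 <- ifelse(rec$her2 >= 0.5, "Positive", "Negative")
  list(
    age_group = factor(age, levels = age_lab),
    size_group = with_missing(size, "size_missing", size_lab),
    node_group = with_missing(node, "nodes_missing", node_lab),
    grade_group = with_missing(grade, "grade_missing", grade_lab),
    her2_group = with_missing(her2, "her2_missing", c("Negative", "Positive"))
  )
}

#' Predicted-risk quantile strata
#'
#' Assigns patients to `k` near-equal bins of predicted cumulative
#' breast-cancer mortality. Ties are broken by a stable sort on
#' (predicted value, id) so the binning is reproducible.
#'
#' @param predictions an `ebc_predictions` data.frame.
#' @param k number of bins (default 5, i.e. quintiles).
#' @return Factor with levels `Q1..Qk` in increasing predicted risk.
#' @export
strata_quantile <- function(predictions, k = 5) {
  if (k < 2) stop("k must be >= 2")
  p <- predictions$cuminc_bc_10
  n <- length(p)
  if (length(unique(p)) < k) stop("not enough distinct predicted values for ", k, " bins")
  ord <- order(p, predictions$id, method = "radix")
  bin <- integer(n)
  bin[ord] <- ceiling(k * seq_len(n) / n)
  factor(paste0("Q", bin), levels = paste0("Q", seq_len(k)))
}

#' Chi-squared statistic from observed and expected counts
#'
#' `chi2 = sum((O - E)^2 / E)` with the upper-tail p-value at `df` degrees
#' of freedom. Bins with `O = E = 0` contribute zero; a bin with `E = 0`
#' but `O > 0` is an error.
#'
#' @param observed,expected aligned non-negative count vectors.
#' @param df degrees of freedom.
#' @return List with `chi2`, `df`, `p`.
#' @export
gof_chi2 <- function(observed, expected, df) {
  if (length(observed) != length(expected)) stop("observed/expected length mismatch")
  bad <- expected == 0 & observed > 0
  if (any(bad)) {
    stop("bins with zero expected but positive observed counts: ",
         paste(which(bad), collapse = ", "))
  }
  term <- ifelse(expected > 0, (observed - expected)^2 / expected, 0)
  chi2 <- sum(term)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Goodness of fit over predicted-risk quantiles
#'
#' Bins patients into `k` quantiles of predicted mortality
#' ([strata_quantile()]), compares observed and expected deaths per bin,
#' and reports the chi-squared statistic with its upper-tail p-value. The
#' degrees of freedom default to `k` — the convention used when quintile
#' calibration is quoted "(5 d.f.)" — but `k - 1` or `k - 2` may be passed.
#'
#' @param cohort an imputed `ebc_cohort`.
#' @param predictions `ebc_predictions` aligned to the cohort.
#' @param k number of quantile bins (default 5).
#' @param df degrees of freedom (default `k`).
#' @param horizon years (default 10).
#' @return List with `chi2`, `df`, `p`, and the per-bin `table`.
#' @export
quantile_gof <- function(cohort, predictions, k = 5, df = k, horizon = 10) {
  strata <- strata_quantile(predictions, k)
  tab <- calibration_table(cohort, predictions, predictions, strata,
                           horizon = horizon)
  res <- gof_chi2(tab$observed_deaths, tab$expected_v2, df)
  res$table <- tab[c("label", "n", "observed_deaths", "expected_v2",
                     "ci_low", "ci_high")]
  names(res$table)[4] <- "expected"
  res
}
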