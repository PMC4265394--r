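# Horizon-restricted discrimination: Mann-Whitney AUC with tie handling,
# the empirical ROC curve, DeLong placement-value variance, and DeLong's
# z-test for the difference of two correlated AUCs.

# Placement values. For each event, the fraction of non-events scored below
# it (ties count 1/2); for each non-event, the fraction of events scored
# above it subtracted from one is NOT what we want -- V01 is the fraction of
# events scored above the non-event, so mean(V10) = mean(V01) = AUC.
placement_values <- function(scores, event) {
  m <- sum(event)
  n <- sum(!event)
  r_all <- rank(scores, ties.method = "average")
  v10 <- (r_all[event] - rank(scores[event], ties.method = "average")) / n
  v01 <- 1 - (r_all[!event] - rank(scores[!event], ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

as_event <- function(statuses) {
  if (is.logical(statuses)) return(statuses)
  if (is.numeric(statuses)) return(statuses != 0)
  s <- as.character(statuses)
  if (any(s == "censored")) {
    stop("censored-before-horizon patients must be removed (or reweighted) ",
         "before computing the AUC; see auc_statuses()")
  }
  if (!all(s %in% c("event", "non_event", "competing_death"))) {
    stop("statuses must be logical, 0/1, or outcome classes from observed_outcomes()")
  }
  s == "event"
}

#' Apply a censoring policy to horizon outcomes
#'
#' Turns the four-level classification from [observed_outcomes()] into the
#' binary event indicator the AUC needs. Under the default `"exclude"`
#' policy, patients censored before the horizon without an event are dropped
#' (`NA`); patients dying of other causes before the horizon are non-events
#' for breast-cancer-specific mortality.
#'
#' @param outcomes factor from [observed_outcomes()].
#' @param policy `"exclude"` (only policy currently implemented; the slot
#'   exists so inverse-probability-of-censoring weighting can be added).
#' @return Logical vector (`TRUE` = event) with `NA` for excluded patients.
#' @export
auc_statuses <- function(outcomes, policy = c("exclude")) {
  policy <- match.arg(policy)
  out <- outcomes == "event"
  out[outcomes == "censored"] <- NA
  out
}

#' Area under the ROC curve with DeLong variance
#'
#' The AUC is the probability that a randomly selected patient who died has
#' a higher predicted mortality than a randomly selected survivor; ties
#' count one half. Computed by midranks (exactly the Mann-Whitney kernel
#' mean) with the DeLong placement-value variance estimate.
#'
#' @param scores predicted mortality per patient.
#' @param statuses logical/0-1 event indicators, or the outcome classes from
#'   [observed_outcomes()] after applying a censoring policy.
#' @return An `auc_result` list: `auc`, `n_pos`, `n_neg`, `variance`, and
#'   `curve` (data.frame of `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, statuses) {
  event <- as_event(statuses)
  keep <- !is.na(event) & !is.na(scores)
  scores <- scores[keep]
  event <- event[keep]
  if (sum(event) == 0 || sum(!event) == 0) {
    stop("AUC needs at least one event and one non-event")
  }
  pv <- placement_values(scores, event)
  auc <- mean(pv$v10)
  variance <- stats::var(pv$v10) / pv$m + stats::var(pv$v01) / pv$n
  if (pv$m == 1) variance <- stats::var(pv$v01) / pv$n
  if (pv$n == 1) variance <- stats::var(pv$v10) / pv$m
  if (pv$m == 1 && pv$n == 1) variance <- 0

  # empirical ROC: sweep thresholds from high to low
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  e <- event[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # collapse tied thresholds
  tpr <- cumsum(e)[last] / pv$m
  fpr <- cumsum(!e)[last] / pv$n
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))

  structure(list(auc = auc, n_pos = pv$m, n_neg = pv$n,
                 variance = variance, curve = curve),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC %.4f (SE %.4f), %d events / %d non-events\n",
              x$auc, sqrt(max(x$variance, 0)), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same patients,
#' accounting for their pairing through the covariance of the DeLong
#' placement values. Reports `delta = auc_b - auc_a`, its variance, the z
#' statistic and the two-sided p-value.
#'
#' @param scores_a,scores_b score vectors aligned to the same patients.
#' @param statuses shared event indicators (as in [roc_auc()]).
#' @return A `delong_result` list: `auc_a`, `auc_b`, `delta`, `var_delta`,
#'   `z`, `p`, `degenerate` (TRUE when the variance of the difference is
#'   zero, e.g. identical scores, in which case `p = 1` with a warning).
#' @export
delong_test <- function(scores_a, scores_b, statuses) {
  if (length(scores_a) != length(scores_b)) stop("score vectors must be aligned")
  event <- as_event(statuses)
  keep <- !is.na(event) & !is.na(scores_a) & !is.na(scores_b)
  event <- event[keep]
  scores_a <- scores_a[keep]
  scores_b <- scores_b[keep]
  if (sum(event) == 0 || sum(!event) == 0) {
    stop("DeLong test needs at least one event and one non-event")
  }
  pa <- placement_values(scores_a, event)
  pb <- placement_values(scores_b, event)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  delta <- auc_b - auc_a
  m <- pa$m; n <- pa$n
  var_delta <- 0
  if (m > 1) var_delta <- var_delta + stats::var(pa$v10 - pb$v10) / m
  if (n > 1) var_delta <- var_delta + stats::var(pa$v01 - pb$v01) / n
  degenerate <- var_delta <= 0
  if (degenerate) {
    warning("degenerate DeLong comparison: zero variance of the AUC difference")
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 var_delta = var_delta, z = z, p = p, degenerate = degenerate,
                 n_pos = m, n_neg = n),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC %.4f vs %.4f, delta %+.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
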