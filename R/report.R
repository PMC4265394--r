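# End-to-end validation report: calibration (overall, clinical strata,
# risk quantiles), goodness of fit, and discrimination with the v2-vs-v3
# comparison, for all patients and the ER-positive subset.

#' Full model-validation report
#'
#' Runs v2 and v3 predictions on an excluded-and-imputed cohort and
#' assembles every assessment in one structure: observed vs expected deaths
#' overall, within the clinical strata of [strata_table_groups()], and
#' within predicted-risk quantiles; the chi-squared goodness of fit over
#' quantiles; AUCs with DeLong variance for both model versions in all
#' patients and in the ER-positive subset; and the DeLong comparison of the
#' two versions. Since the two versions coincide for ER-negative disease,
#' reports on an all-ER-negative cohort have identical v2 and v3 sections.
#'
#' @param cohort an `ebc_cohort` that has been through
#'   [apply_staging_exclusion()] and [impute_missing()].
#' @param config model configuration.
#' @param k quantile bins for calibration/GOF (default 5).
#' @param gof_df degrees of freedom for the GOF test (default `k`).
#' @param horizon years (default `config$horizon_years`).
#' @param out_dir if given, the report is written as `report.json` plus
#'   calibration and ROC plots (PDF) into this directory.
#' @return A nested list (JSON-ready). When fewer than two outcome classes
#'   remain after the censoring policy, the discrimination section is marked
#'   unavailable instead of failing.
#' @export
validation_report <- function(cohort, config, k = 5, gof_df = k,
                              horizon = NULL, out_dir = NULL) {
  config <- validate_model_config(config)
  if (is.null(horizon)) horizon <- config$horizon_years
  pred2 <- predict_cohort(cohort, config, "v2")
  pred3 <- predict_cohort(cohort, config, "v3")
  obs <- observed_outcomes(cohort, horizon)
  status <- auc_statuses(obs)
  rec <- as_record_df(cohort)

  overall <- calibration_table(cohort, pred2, pred3,
                               rep("all", nrow(rec)), horizon)
  strata <- strata_table_groups(cohort)
  by_strata <- lapply(strata, function(s) {
    calibration_table(cohort, pred2, pred3, s, horizon)
  })
  quant <- tryCatch(
    calibration_table(cohort, pred2, pred3, strata_quantile(pred3, k), horizon),
    error = function(e) NULL)

  gof <- lapply(list(v2 = pred2, v3 = pred3), function(p) {
    tryCatch({
      g <- quantile_gof(cohort, p, k = k, df = gof_df, horizon = horizon)
      g[c("chi2", "df", "p")]
    }, error = function(e) list(error = conditionMessage(e)))
  })

  discrim <- function(idx) {
    st <- status[idx]
    ok <- sum(st, na.rm = TRUE) >= 1 && sum(!st, na.rm = TRUE) >= 1 &&
      sum(!is.na(st)) >= 2
    if (!ok) return(list(available = FALSE))
    a2 <- roc_auc(pred2$cuminc_bc_10[idx], st)
    a3 <- roc_auc(pred3$cuminc_bc_10[idx], st)
    dl <- suppressWarnings(
      delong_test(pred2$cuminc_bc_10[idx], pred3$cuminc_bc_10[idx], st))
    list(available = TRUE,
         auc_v2 = a2$auc, var_v2 = a2$variance,
         auc_v3 = a3$auc, var_v3 = a3$variance,
         n_events = a2$n_pos, n_nonevents = a2$n_neg,
         delong = dl[c("delta", "var_delta", "z", "p", "degenerate")])
  }

  report <- list(
    cohort = list(
      n = nrow(rec),
      n_er_pos = sum(rec$er == "pos"),
      n_er_neg = sum(rec$er == "neg"),
      horizon_years = horizon,
      observed_deaths = sum(obs == "event"),
      censoring_policy = "exclude",
      imputation_log = cohort$imputation_log
    ),
    calibration = list(
      overall = overall,
      by_stratum = by_strata,
      by_quantile = quant
    ),
    gof = gof,
    discrimination = list(
      all_patients = discrim(rep(TRUE, nrow(rec))),
      er_positive = discrim(rec$er == "pos")
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    if (!is.null(quant)) {
      grDevices::pdf(file.path(out_dir, "calibration.pdf"), width = 6, height = 6)
      plot_calibration(quant)
      grDevices::dev.off()
    }
    if (isTRUE(report$discrimination$all_patients$available)) {
      grDevices::pdf(file.path(out_dir, "roc.pdf"), width = 6, height = 6)
      plot_roc(pred2, pred3, status)
      grDevices::dev.off()
    }
  }
  report
}

#' Calibration plot by risk quantile
#'
#' Observed deaths with exact Poisson 95% intervals against expected deaths
#' per quantile bin, for each model version, with the identity line.
#'
#' @param quant_table a calibration table over quantile strata.
#' @export
plot_calibration <- function(quant_table) {
  xmax <- max(quant_table$expected_v2, quant_table$expected_v3,
              quant_table$ci_high)
  plot(NA, xlim = c(0, xmax * 1.05), ylim = c(0, xmax * 1.05),
       xlab = "Expected breast-cancer deaths",
       ylab = "Observed breast-cancer deaths (95% CI)",
       main = "Calibration by predicted-risk quantile")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  for (i in seq_len(nrow(quant_table))) {
    graphics::segments(quant_table$expected_v3[i], quant_table$ci_low[i],
                       quant_table$expected_v3[i], quant_table$ci_high[i],
                       col = "firebrick")
    graphics::segments(quant_table$expected_v2[i], quant_table$ci_low[i],
                       quant_table$expected_v2[i], quant_table$ci_high[i],
                       col = "steelblue")
  }
  graphics::points(quant_table$expected_v2, quant_table$observed_deaths,
                   pch = 19, col = "steelblue")
  graphics::points(quant_table$expected_v3, quant_table$observed_deaths,
                   pch = 17, col = "firebrick")
  graphics::legend("topleft", legend = c("v2", "v3"), pch = c(19, 17),
                   col = c("steelblue", "firebrick"), bty = "n")
}

#' ROC curves for two model versions
#'
#' @param pred2,pred3 `ebc_predictions` for v2 and v3.
#' @param statuses event indicators (NA = excluded).
#' @export
plot_roc <- function(pred2, pred3, statuses) {
  r2 <- roc_auc(pred2$cuminc_bc_10, statuses)
  r3 <- roc_auc(pred3$cuminc_bc_10, statuses)
  plot(r2$curve$fpr, r2$curve$tpr, type = "l", col = "steelblue", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       main = "ROC for breast-cancer mortality at horizon")
  graphics::lines(r3$curve$fpr, r3$curve$tpr, col = "firebrick", lwd = 2)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = c("steelblue", "firebrick"),
                   legend = sprintf("%s (AUC %.4f)", c("v2", "v3"),
                                    c(r2$auc, r3$auc)))
}
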