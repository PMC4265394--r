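# Multiplicative proportional-hazards prediction engine.
#
# A patient's annual breast-cancer hazard is the ER-stratum baseline hazard
# times a relative hazard built from category codes (nodes, size, grade),
# screen detection, and mean-one renormalized marker terms (HER2 always;
# KI67 in v3 for ER+ disease), times adjuvant-treatment multipliers.
# Other-cause mortality comes from a life table at the attained age, and the
# two causes compete on a discrete annual grid.

#' Category code for number of positive nodes
#'
#' Maps positive-node counts to the unit codes 0-4 of the categories
#' 0, 1, 2-4, 5-9, 10+.
#'
#' @param nodes_pos non-negative counts (NA passes through).
#' @return Numeric codes 0-4.
#' @export
node_code <- function(nodes_pos) {
  code <- findInterval(nodes_pos, c(0, 1, 2, 5, 10)) - 1
  code[!is.na(nodes_pos) & nodes_pos < 0] <- NA
  code
}

#' Category code for tumour size
#'
#' Maps size in mm to the unit codes 0-4 of the categories
#' <10, 10-19, 20-29, 30-49, 50+ mm.
#'
#' @param size_mm positive sizes in mm (NA passes through).
#' @return Numeric codes 0-4.
#' @export
size_code <- function(size_mm) {
  code <- findInterval(size_mm, c(0, 10, 20, 30, 50)) - 1
  code[!is.na(size_mm) & size_mm <= 0] <- NA
  code
}

#' Split a marker hazard ratio into mean-one relative hazards
#'
#' Solves the two constraints `h_pos = hr * h_neg` and
#' `prevalence * h_pos + (1 - prevalence) * h_neg = 1`, so that adding the
#' marker leaves the prevalence-averaged hazard unchanged. With the KI67
#' hazard ratio of 1.3 and prevalence 0.412 this yields relative hazards of
#' 0.89 (negative) and 1.16 (positive) after rounding.
#'
#' @param hr positive-to-negative hazard ratio (> 0).
#' @param prevalence marker positivity proportion, strictly inside (0, 1).
#' @return List with exact (unrounded) `h_neg` and `h_pos`.
#' @export
renormalize_marker <- function(hr, prevalence) {
  if (!is.numeric(hr) || hr <= 0) stop("marker hr must be > 0")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("marker prevalence must lie strictly in (0, 1)")
  }
  h_neg <- 1 / ((1 - prevalence) + prevalence * hr)
  list(h_neg = h_neg, h_pos = hr * h_neg)
}

# Marker multiplier for a (possibly fractional) status m in [0,1]:
# (1 - m) * h_neg + m * h_pos. At m = prevalence this is exactly 1.
marker_term <- function(status, hr, prevalence) {
  mh <- renormalize_marker(hr, prevalence)
  (1 - status) * mh$h_neg + status * mh$h_pos
}

# Vectorized relative hazard over the rows of a records data.frame.
# Fractional codes (from mean imputation) enter as fractional exponents;
# fractional marker statuses as prevalence weights.
rel_hazard_records <- function(rec, config, version) {
  version <- match.arg(version, c("v2", "v3"))
  if (any(is.na(rec$er)) || !all(rec$er %in% c("pos", "neg"))) {
    stop("relative hazard requires known ER status for every record")
  }
  pos <- rec$er == "pos"

  ncode <- if (!is.null(rec$node_code)) rec$node_code else node_code(rec$nodes_pos)
  scode <- size_code(rec$size_mm)
  gcode <- rec$grade
  bad <- is.na(ncode) | is.na(scode) | is.na(gcode) |
    is.na(rec$her2) | (version == "v3" & pos & is.na(rec$ki67))
  if (any(bad)) {
    stop("records not fully coded (impute first): ",
         paste(utils::head(rec$id[bad], 5), collapse = ", "))
  }
  if (any(ncode < 0 | scode < 0 | gcode < 0)) {
    stop("negative category code")
  }

  par <- function(field) {
    ifelse(pos, config$er_pos[[field]], config$er_neg[[field]])
  }
  rh <- par("hr_node")^ncode * par("hr_size")^scode * par("hr_grade")^gcode
  screen <- !is.na(rec$detection) & rec$detection == "screen"
  rh <- rh * ifelse(screen, par("hr_screen"), 1)

  # optional age hook: per-decade HR centred at age 50 (off unless configured)
  has_age <- !is.null(config$er_pos$hr_age_per_decade) ||
    !is.null(config$er_neg$hr_age_per_decade)
  if (has_age) {
    hr_age <- ifelse(pos,
                     config$er_pos$hr_age_per_decade %||% 1,
                     config$er_neg$hr_age_per_decade %||% 1)
    rh <- rh * hr_age^((rec$age_dx - 50) / 10)
  }

  rh <- rh * marker_term(rec$her2, config$her2$hr, config$her2$prevalence)
  if (version == "v3") {
    k <- marker_term(rec$ki67, config$ki67$hr, config$ki67$prevalence)
    rh <- rh * ifelse(pos, k, 1)
  }
  rh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative breast-cancer hazard for one patient
#'
#' Product of the per-unit hazard ratios raised to the patient's category
#' codes (positive nodes, tumour size, grade), the screen-detection
#' multiplier when the tumour was screen detected, the mean-one HER2 term,
#' and — for v3 in ER-positive disease — the mean-one KI67 term. Fractional
#' codes and marker statuses produced by mean imputation are honoured
#' (fractional exponents; prevalence-weighted marker terms).
#'
#' @param record a single-row data.frame (or one-record cohort) in the
#'   canonical schema, fully coded.
#' @param config model configuration ([default_model_config()]).
#' @param version `"v2"` (clinicopathological + HER2) or `"v3"` (+ KI67).
#' @return A positive scalar.
#' @export
relative_hazard <- function(record, config, version = c("v2", "v3")) {
  rec <- as_record_df(record)
  config <- validate_model_config(config)
  rel_hazard_records(rec, config, match.arg(version))
}

as_record_df <- function(record) {
  if (inherits(record, "ebc_cohort")) return(record$records)
  if (is.data.frame(record)) return(record)
  as.data.frame(record, stringsAsFactors = FALSE)
}

# Multiplier on the breast-cancer hazard for the therapy actually received.
therapy_multiplier <- function(therapy, treatment) {
  if (any(!therapy %in% THERAPY_LEVELS)) stop("unknown therapy value")
  mult <- c(none = 1,
            chemo = treatment$chemo,
            endocrine = treatment$endocrine,
            both = treatment$chemo * treatment$endocrine)
  if (any(mult <= 0)) stop("treatment multipliers must be > 0")
  unname(mult[therapy])
}

# Core curve computation, vectorized over patients. Returns matrices with
# H + 1 columns (years 0..H). Competing risks on the annual grid: within
# each year the probability of dying, S * (1 - exp(-h_total)), is split
# between causes proportionally to their hazards, which conserves
# S + cuminc_bc + cuminc_oc = 1 exactly.
compute_curves <- function(rec, config, version, therapy = rec$therapy) {
  H <- config$horizon_years
  rh <- rel_hazard_records(rec, config, version)
  tmult <- therapy_multiplier(therapy, config$treatment)
  n <- nrow(rec)
  pos <- rec$er == "pos"
  base <- matrix(0, n, H)
  if (any(pos)) {
    base[pos, ] <- matrix(config$er_pos$baseline_annual_hazard[seq_len(H)],
                          sum(pos), H, byrow = TRUE)
  }
  if (any(!pos)) {
    base[!pos, ] <- matrix(config$er_neg$baseline_annual_hazard[seq_len(H)],
                           sum(!pos), H, byrow = TRUE)
  }
  h_bc <- base * (rh * tmult)
  attained <- outer(floor(rec$age_dx), seq_len(H) - 1, "+")
  h_oc <- matrix(life_table_hazard(config, attained), n, H)

  s_bc <- cbind(1, exp(-t(apply(h_bc, 1, cumsum))))
  s_oc <- cbind(1, exp(-t(apply(h_oc, 1, cumsum))))
  if (H == 1) { # apply() drops dimensions for a single year
    s_bc <- cbind(1, exp(-h_bc))
    s_oc <- cbind(1, exp(-h_oc))
  }

  cuminc_bc <- matrix(0, n, H + 1)
  cuminc_oc <- matrix(0, n, H + 1)
  surv <- rep(1, n)
  for (t in seq_len(H)) {
    h <- h_bc[, t] + h_oc[, t]
    p_die <- surv * (1 - exp(-h))
    frac_bc <- ifelse(h > 0, h_bc[, t] / h, 0)
    cuminc_bc[, t + 1] <- cuminc_bc[, t] + p_die * frac_bc
    cuminc_oc[, t + 1] <- cuminc_oc[, t] + p_die * (1 - frac_bc)
    surv <- surv * exp(-h)
  }
  yrs <- 0:H
  dimnames(s_bc) <- dimnames(s_oc) <- dimnames(cuminc_bc) <-
    dimnames(cuminc_oc) <- list(rec$id, paste0("year", yrs))
  list(s_bc = s_bc, s_oc = s_oc,
       cuminc_bc = cuminc_bc, cuminc_oc = cuminc_oc)
}

#' Annual survival and cumulative mortality for one patient
#'
#' Builds the patient's annual breast-cancer and other-cause survival curves
#' and cause-specific cumulative mortality over the configured horizon,
#' under the therapy recorded for the patient, and attaches absolute
#' treatment benefits from [treatment_benefit()].
#'
#' @inheritParams relative_hazard
#' @return A `RiskPrediction` list: `s_bc`, `s_oc`, `cuminc_bc`, `cuminc_oc`
#'   (named vectors for years 0..H), `version`, and `benefits` (data.frame
#'   of absolute overall-survival gains at 5 and 10 years per therapy
#'   option).
#' @export
survival_curves <- function(record, config, version = c("v2", "v3")) {
  version <- match.arg(version)
  rec <- as_record_df(record)
  if (nrow(rec) != 1) stop("survival_curves expects a single record; use predict_cohort")
  config <- validate_model_config(config)
  cv <- compute_curves(rec, config, version)
  structure(
    list(s_bc = cv$s_bc[1, ], s_oc = cv$s_oc[1, ],
         cuminc_bc = cv$cuminc_bc[1, ], cuminc_oc = cv$cuminc_oc[1, ],
         version = version,
         benefits = treatment_benefit(rec, config, version)),
    class = "risk_prediction"
  )
}

#' @export
print.risk_prediction <- function(x, ...) {
  H <- length(x$s_bc) - 1
  cat("<risk_prediction> ", x$version, ", horizon ", H, " years\n", sep = "")
  cat(sprintf("  %d-year: S_bc %.3f, S_oc %.3f, cuminc_bc %.3f, cuminc_oc %.3f\n",
              H, x$s_bc[H + 1], x$s_oc[H + 1],
              x$cuminc_bc[H + 1], x$cuminc_oc[H + 1]))
  b <- x$benefits
  b$benefit_5 <- round(b$benefit_5, 4)
  b$benefit_10 <- round(b$benefit_10, 4)
  print(b)
  invisible(x)
}

#' Absolute treatment benefit for one patient
#'
#' For each adjuvant option (endocrine, chemotherapy, both) the breast-cancer
#' hazard is multiplied by the option's hazard multiplier (combined therapy
#' multiplies both) and the curves recomputed; the benefit is the treated
#' minus untreated overall survival at 5 and at 10 years (or the horizon, if
#' shorter).
#'
#' @inheritParams relative_hazard
#' @return data.frame with columns `therapy`, `benefit_5`, `benefit_10`.
#' @export
treatment_benefit <- function(record, config, version = c("v2", "v3")) {
  version <- match.arg(version)
  rec <- as_record_df(record)
  config <- validate_model_config(config)
  bm <- benefit_matrix(rec, config, version)
  data.frame(therapy = c("endocrine", "chemo", "both"),
             benefit_5 = c(bm$b5), benefit_10 = c(bm$b10),
             row.names = NULL, stringsAsFactors = FALSE)
}

benefit_matrix <- function(rec, config, version) {
  H <- config$horizon_years
  y5 <- min(5, H)
  overall_at <- function(cv, t) cv$s_bc[, t + 1] * cv$s_oc[, t + 1]
  none <- compute_curves(rec, config, version, therapy = rep("none", nrow(rec)))
  b5 <- b10 <- matrix(0, nrow(rec), 3,
                      dimnames = list(rec$id, c("endocrine", "chemo", "both")))
  for (opt in c("endocrine", "chemo", "both")) {
    tr <- compute_curves(rec, config, version, therapy = rep(opt, nrow(rec)))
    b5[, opt] <- overall_at(tr, y5) - overall_at(none, y5)
    b10[, opt] <- overall_at(tr, H) - overall_at(none, H)
  }
  list(b5 = b5, b10 = b10)
}

#' Predict survival for every patient in a cohort
#'
#' Vectorized prediction under the therapy each patient actually received.
#' v2 and v3 differ only through the KI67 term, so they coincide for
#' ER-negative records.
#'
#' @param cohort an imputed `ebc_cohort` (see [impute_missing()]).
#' @param config model configuration.
#' @param version `"v2"` or `"v3"`.
#' @return A data.frame of class `ebc_predictions`, one row per patient:
#'   `id`, `version`, `s_bc_5`, `s_bc_10`, `cuminc_bc_10`, `cuminc_oc_10`,
#'   and 10-year benefits `benefit_endocrine_10`, `benefit_chemo_10`,
#'   `benefit_both_10` (`_10` columns are at the horizon when it is not 10).
#'   Full annual curves are attached as the `"curves"` attribute.
#' @export
predict_cohort <- function(cohort, config, version = c("v2", "v3")) {
  version <- match.arg(version)
  rec <- as_record_df(cohort)
  config <- validate_model_config(config)
  H <- config$horizon_years
  if (nrow(rec) == 0) {
    out <- data.frame(id = character(), version = character(),
                      s_bc_5 = numeric(), s_bc_10 = numeric(),
                      cuminc_bc_10 = numeric(), cuminc_oc_10 = numeric(),
                      benefit_endocrine_10 = numeric(),
                      benefit_chemo_10 = numeric(),
                      benefit_both_10 = numeric())
    class(out) <- c("ebc_predictions", class(out))
    return(out)
  }
  cv <- compute_curves(rec, config, version)
  bm <- benefit_matrix(rec, config, version)
  y5 <- min(5, H)
  out <- data.frame(
    id = rec$id,
    version = version,
    s_bc_5 = cv$s_bc[, y5 + 1],
    s_bc_10 = cv$s_bc[, H + 1],
    cuminc_bc_10 = cv$cuminc_bc[, H + 1],
    cuminc_oc_10 = cv$cuminc_oc[, H + 1],
    benefit_endocrine_10 = bm$b10[, "endocrine"],
    benefit_chemo_10 = bm$b10[, "chemo"],
    benefit_both_10 = bm$b10[, "both"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "curves") <- cv
  class(out) <- c("ebc_predictions", class(out))
  out
}

#' Write cohort predictions to CSV
#'
#' @param predictions an `ebc_predictions` data.frame from [predict_cohort()].
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE)
  invisible(path)
}
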