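# Cohort container and CSV I/O.
#
# A cohort is a plain data.frame of patient records wrapped in a light S3
# class that carries provenance and an imputation log. Columns follow the
# canonical schema (see read_cohort); markers and grade are stored as
# numeric codes so that fractional values produced by mean imputation flow
# through the prediction engine unchanged.

COHORT_COLUMNS <- c(
  "id", "age_dx", "size_mm", "grade", "nodes_pos", "nodes_sampled",
  "er", "her2", "ki67", "detection", "therapy", "follow_up_years", "outcome"
)

OUTCOME_LEVELS <- c("censored", "bc_death", "other_death")
THERAPY_LEVELS <- c("none", "chemo", "endocrine", "both")

#' Construct a cohort object
#'
#' Wraps a data.frame of patient records into an `ebc_cohort`. Used by
#' [read_cohort()] and the synthetic-cohort generator; call it directly only
#' when building records programmatically.
#'
#' @param records data.frame with the canonical cohort columns: `id`
#'   (character, unique), `age_dx` (years), `size_mm` (mm, `NA` allowed),
#'   `grade` (numeric code 0 = low, 1 = intermediate, 2 = high, fractional
#'   allowed after imputation, `NA` allowed), `nodes_pos`, `nodes_sampled`
#'   (non-negative counts, `NA` allowed), `er` (`"pos"`/`"neg"`, never
#'   missing), `her2`, `ki67` (numeric status in `[0, 1]`: 1 = positive,
#'   0 = negative, fractional after imputation, `NA` allowed), `detection`
#'   (`"screen"`/`"symptomatic"`/`NA`), `therapy` (`"none"`, `"chemo"`,
#'   `"endocrine"`, or `"both"`), `follow_up_years` (non-negative), `outcome`
#'   (`"censored"`, `"bc_death"`, or `"other_death"`).
#' @param provenance free-text label recording where the records came from.
#' @param imputation_log data.frame with columns `variable`, `n_imputed`,
#'   `value`; empty until [impute_missing()] runs.
#' @return An `ebc_cohort` object.
#' @export
new_cohort <- function(records, provenance = "unspecified",
                       imputation_log = empty_imputation_log()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort records lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop("duplicate patient ids in cohort: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(is.na(records$er)) || !all(records$er %in% c("pos", "neg"))) {
    stop("er status must be 'pos' or 'neg' for every record (never missing)")
  }
  rownames(records) <- NULL
  structure(
    list(records = records, provenance = provenance,
         imputation_log = imputation_log),
    class = "ebc_cohort"
  )
}

empty_imputation_log <- function() {
  data.frame(variable = character(), n_imputed = integer(),
             value = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.ebc_cohort <- function(x, ...) {
  rec <- x$records
  cat("<ebc_cohort> ", nrow(rec), " patients (", x$provenance, ")\n", sep = "")
  if (nrow(rec) > 0) {
    cat("  ER+: ", sum(rec$er == "pos"), "   ER-: ", sum(rec$er == "neg"), "\n", sep = "")
    cat("  outcomes: ", paste(names(table(rec$outcome)), table(rec$outcome),
                              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$imputation_log) > 0) {
    cat("  imputed: ", paste(x$imputation_log$variable,
                             x$imputation_log$n_imputed,
                             sep = "x", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.ebc_cohort <- function(x, ...) x$records

#' Number of patients in a cohort
#' @param x an `ebc_cohort`.
#' @export
n_patients <- function(x) nrow(x$records)

parse_grade <- function(raw) {
  out <- rep(NA_real_, length(raw))
  raw <- trimws(as.character(raw))
  blank <- is.na(raw) | raw == ""
  word <- match(tolower(raw), c("low", "intermediate", "high"))
  out[!is.na(word)] <- word[!is.na(word)] - 1
  rest <- !blank & is.na(word)
  num <- suppressWarnings(as.numeric(raw[rest]))
  # numeric 1/2/3 are clinical grades; fractional values are imputed codes
  num <- ifelse(!is.na(num) & num >= 1 & num <= 3 & num == round(num), num - 1, num)
  out[rest] <- num
  bad <- rest & is.na(out) | (!is.na(out) & (out < 0 | out > 2))
  list(value = out, bad = which(bad))
}

parse_marker <- function(raw) {
  out <- rep(NA_real_, length(raw))
  raw <- trimws(tolower(as.character(raw)))
  blank <- is.na(raw) | raw == ""
  out[raw %in% "pos"] <- 1
  out[raw %in% "neg"] <- 0
  rest <- !blank & !(raw %in% c("pos", "neg"))
  num <- suppressWarnings(as.numeric(raw[rest]))
  out[rest] <- num
  bad <- rest & is.na(out) | (!is.na(out) & (out < 0 | out > 1))
  list(value = out, bad = which(bad))
}

parse_num <- function(raw) {
  raw <- trimws(as.character(raw))
  blank <- is.na(raw) | raw == ""
  num <- suppressWarnings(as.numeric(raw))
  list(value = num, bad = which(!blank & is.na(num)))
}

#' Read a patient cohort from CSV
#'
#' Reads the canonical cohort CSV
#' (`id,age_dx,size_mm,grade,nodes_pos,nodes_sampled,er,her2,ki67,detection,therapy,follow_up_years,outcome`),
#' validates every row, and returns an [new_cohort()] object. Missing values
#' are empty cells; `grade` accepts `1/2/3`, `low/intermediate/high`, or a
#' fractional imputed code; `her2`/`ki67` accept `pos`/`neg` or a fractional
#' status in `[0, 1]`; `outcome` is one of `censored`, `bc_death`,
#' `other_death`.
#'
#' @param path CSV file path.
#' @param schema_strict if `TRUE` (default) the header must contain exactly
#'   the canonical columns; if `FALSE` extra columns are ignored.
#' @return An `ebc_cohort`.
#' @details Rows violating the schema (non-numeric size or node counts,
#'   unknown categories, negative follow-up, `nodes_pos > nodes_sampled`)
#'   are reported together with their row numbers and reading fails; a
#'   missing mandatory column fails immediately.
#' @export
read_cohort <- function(path, schema_strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (schema_strict && length(extra) > 0) {
    stop("unexpected column(s) in cohort CSV (schema_strict): ",
         paste(extra, collapse = ", "))
  }
  cohort_from_raw(raw[COHORT_COLUMNS], provenance = path)
}

# Shared row-level validation for read_cohort and programmatic construction
# from character data. `raw` holds character columns in canonical order.
cohort_from_raw <- function(raw, provenance) {
  n <- nrow(raw)
  row_errors <- list()
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      row_errors[[length(row_errors) + 1]] <<- paste0(
        msg, " (row", if (length(rows) > 1) "s" else "", " ",
        paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ")")
    }
  }

  blank <- function(x) is.na(x) | trimws(x) == ""

  age <- parse_num(raw$age_dx)
  note(age$bad, "non-numeric age_dx")
  note(which(!is.na(age$value) & age$value <= 0), "age_dx must be positive")
  note(which(blank(raw$age_dx)), "age_dx is mandatory")

  size <- parse_num(raw$size_mm)
  note(size$bad, "non-numeric size_mm")
  note(which(!is.na(size$value) & size$value <= 0), "size_mm must be positive")

  grade <- parse_grade(raw$grade)
  note(grade$bad, "unparseable grade")

  nodes_pos <- parse_num(raw$nodes_pos)
  note(nodes_pos$bad, "non-numeric nodes_pos")
  nodes_sampled <- parse_num(raw$nodes_sampled)
  note(nodes_sampled$bad, "non-numeric nodes_sampled")
  note(which(!is.na(nodes_pos$value) & nodes_pos$value < 0), "nodes_pos must be >= 0")
  both <- !is.na(nodes_pos$value) & !is.na(nodes_sampled$value)
  note(which(both & nodes_pos$value > nodes_sampled$value),
       "nodes_pos exceeds nodes_sampled")

  er <- tolower(trimws(raw$er))
  note(which(!(er %in% c("pos", "neg"))), "er must be pos or neg")

  her2 <- parse_marker(raw$her2)
  note(her2$bad, "unparseable her2 status")
  ki67 <- parse_marker(raw$ki67)
  note(ki67$bad, "unparseable ki67 status")

  det <- tolower(trimws(raw$detection))
  det[blank(raw$detection)] <- NA_character_
  note(which(!is.na(det) & !(det %in% c("screen", "symptomatic"))),
       "detection must be screen, symptomatic, or empty")

  ther <- tolower(trimws(raw$therapy))
  ther[blank(raw$therapy)] <- "none"
  note(which(!(ther %in% THERAPY_LEVELS)), "unknown therapy")

  fu <- parse_num(raw$follow_up_years)
  note(fu$bad, "non-numeric follow_up_years")
  note(which(blank(raw$follow_up_years)), "follow_up_years is mandatory")
  note(which(!is.na(fu$value) & fu$value < 0), "follow_up_years must be >= 0")

  outc <- tolower(trimws(raw$outcome))
  note(which(!(outc %in% OUTCOME_LEVELS)), "unknown outcome")

  if (length(row_errors) > 0) {
    stop("cohort row errors:\n  ", paste(unlist(row_errors), collapse = "\n  "))
  }

  records <- data.frame(
    id = as.character(raw$id),
    age_dx = age$value,
    size_mm = size$value,
    grade = grade$value,
    nodes_pos = nodes_pos$value,
    nodes_sampled = nodes_sampled$value,
    er = er,
    her2 = her2$value,
    ki67 = ki67$value,
    detection = det,
    therapy = ther,
    follow_up_years = fu$value,
    outcome = outc,
    stringsAsFactors = FALSE
  )
  new_cohort(records, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: integer marker statuses are written back as
#' `pos`/`neg` and integer grade codes as clinical grades `1/2/3`, so a
#' read-write-read cycle round-trips exactly; fractional (imputed) values are
#' written numerically.
#'
#' @param cohort an `ebc_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rec <- cohort$records
  fmt_marker <- function(x) {
    out <- ifelse(is.na(x), "",
                  ifelse(x == 1, "pos", ifelse(x == 0, "neg", format(x, digits = 15))))
    out
  }
  out <- data.frame(
    id = rec$id,
    age_dx = rec$age_dx,
    size_mm = ifelse(is.na(rec$size_mm), "", format(rec$size_mm, digits = 15, trim = TRUE)),
    grade = ifelse(is.na(rec$grade), "",
                   ifelse(rec$grade %in% 0:2, as.character(rec$grade + 1),
                          format(rec$grade, digits = 15, trim = TRUE))),
    nodes_pos = ifelse(is.na(rec$nodes_pos), "", format(rec$nodes_pos, digits = 15, trim = TRUE)),
    nodes_sampled = ifelse(is.na(rec$nodes_sampled), "", format(rec$nodes_sampled, digits = 15, trim = TRUE)),
    er = rec$er,
    her2 = fmt_marker(rec$her2),
    ki67 = fmt_marker(rec$ki67),
    detection = ifelse(is.na(rec$detection), "", rec$detection),
    therapy = rec$therapy,
    follow_up_years = rec$follow_up_years,
    outcome = rec$outcome,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude inadequately staged node-negative patients
#'
#' Removes records that are node negative (`nodes_pos == 0`) with fewer than
#' four axillary nodes sampled, for whom node-negative status cannot be
#' asserted reliably. Records with missing staging fields are retained: the
#' exclusion targets inadequately staged node-negative cases only.
#'
#' @param cohort an `ebc_cohort`.
#' @return The filtered cohort; the number excluded is recorded in the
#'   `staging_excluded` attribute and the operation is idempotent.
#' @export
apply_staging_exclusion <- function(cohort) {
  rec <- cohort$records
  drop <- !is.na(rec$nodes_pos) & rec$nodes_pos == 0 &
    !is.na(rec$nodes_sampled) & rec$nodes_sampled < 4
  out <- new_cohort(rec[!drop, , drop = FALSE],
                    provenance = cohort$provenance,
                    imputation_log = cohort$imputation_log)
  if (!is.null(attr(cohort, "true_records"))) {
    attr(out, "true_records") <- attr(cohort, "true_records")[!drop, , drop = FALSE]
  }
  attr(out, "staging_excluded") <- sum(drop)
  out
}

#' Mean-impute missing covariates
#'
#' Replaces missing tumour size by the cohort mean of observed sizes, missing
#' grade by the mean observed grade code (0/1/2 scale, stored as a fractional
#' code), and missing HER2/KI67 status by the observed positivity proportion
#' (stored as a fractional status in `[0, 1]`, consumed downstream as a
#' prevalence weight). Records with missing `nodes_pos` receive the cohort
#' mean of the observed node-category codes in the auxiliary `node_code`
#' column, which the prediction engine prefers over `nodes_pos` when present.
#'
#' @param cohort an `ebc_cohort`.
#' @return The imputed cohort; `imputation_log` lists, per variable, how many
#'   values were imputed and the value used. A cohort without missing values
#'   comes back unchanged with an empty log. Pre-imputation missingness is
#'   preserved in logical `*_missing` columns so that calibration strata can
#'   still report "Missing" groups.
#' @export
impute_missing <- function(cohort) {
  rec <- cohort$records
  log <- empty_imputation_log()
  add_log <- function(variable, n, value) {
    rbind(log, data.frame(variable = variable, n_imputed = n, value = value,
                          stringsAsFactors = FALSE))
  }
  impute_num <- function(x, name) {
    miss <- is.na(x)
    if (any(miss)) {
      if (all(miss)) stop("cannot impute '", name, "': no observed values")
      m <- mean(x[!miss])
      x[miss] <- m
      log <<- add_log(name, sum(miss), m)
    }
    x
  }

  rec$size_missing <- is.na(rec$size_mm)
  rec$grade_missing <- is.na(rec$grade)
  rec$her2_missing <- is.na(rec$her2)
  rec$ki67_missing <- is.na(rec$ki67)
  rec$nodes_missing <- is.na(rec$nodes_pos)

  rec$size_mm <- impute_num(rec$size_mm, "size_mm")
  rec$grade <- impute_num(rec$grade, "grade")
  rec$her2 <- impute_num(rec$her2, "her2")
  rec$ki67 <- impute_num(rec$ki67, "ki67")

  # nodes are imputed on the category-code scale (0,1,2-4,5-9,10+ -> 0..4)
  codes <- node_code(rec$nodes_pos)
  miss <- is.na(codes)
  if (any(miss)) {
    if (all(miss)) stop("cannot impute 'nodes_pos': no observed values")
    m <- mean(codes[!miss])
    codes[miss] <- m
    log <- add_log("node_code", sum(miss), m)
  }
  rec$node_code <- codes

  out <- new_cohort(rec, provenance = cohort$provenance, imputation_log = log)
  attr(out, "true_records") <- attr(cohort, "true_records")
  out
}
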