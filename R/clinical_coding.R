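# Eligibility screening, KDIGO AKI detection/staging from serum
# creatinine series, and discretization of admission labs into the
# analysis bands.

# KDIGO serum-creatinine thresholds, converted to umol/L
# (1 mg/dL = 88.4 umol/L).
KDIGO_DELTA_48H <- 26.5    # 0.3 mg/dL absolute rise within 48 h
KDIGO_ABS_STAGE3 <- 353.6  # 4.0 mg/dL
KDIGO_FOLD_WINDOW <- 168   # 7 days, hours
KDIGO_DELTA_WINDOW <- 48

#' Apply the cohort eligibility filters
#'
#' Excludes admissions shorter than 24 hours, patients on dialysis or
#' renal replacement therapy at baseline, and patients without repeated
#' serum-creatinine tests. Reasons are tallied in that fixed order; a
#' patient counts once, under the first reason that applies.
#'
#' @param cohort An \code{aki_cohort} or list of patient records.
#' @return List with \code{eligible} (records) and \code{exclusion_log}
#'   (named integer vector: \code{los_lt_24h}, \code{baseline_rrt},
#'   \code{insufficient_scr}).
#' @export
apply_eligibility <- function(cohort) {
  log <- c(los_lt_24h = 0L, baseline_rrt = 0L, insufficient_scr = 0L)
  keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    if (p$los_hours < 24) {
      log[["los_lt_24h"]] <- log[["los_lt_24h"]] + 1L
    } else if (isTRUE(p$dialysis_or_rrt_at_baseline)) {
      log[["baseline_rrt"]] <- log[["baseline_rrt"]] + 1L
    } else if (NROW(p$scr_series) < 2L) {
      log[["insufficient_scr"]] <- log[["insufficient_scr"]] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  eligible <- cohort[keep]
  attrs <- attributes(cohort)
  if (!is.null(attrs$truth) && NROW(attrs$truth)) {
    attr(eligible, "truth") <- attrs$truth[keep, , drop = FALSE]
  }
  class(eligible) <- "aki_cohort"
  list(eligible = eligible, exclusion_log = log)
}

#' Detect and stage AKI from a serum-creatinine series (KDIGO)
#'
#' AKI is present when either clause of the KDIGO creatinine definition
#' holds: an absolute rise of >= 26.5 umol/L (0.3 mg/dL) between two
#' measurements at most 48 h apart, or a measurement reaching >= 1.5x
#' the rolling baseline (the minimum SCr in the preceding 168 h). The
#' stage is the maximum attained over the admission: stage 1 for the
#' absolute-rise clause or a 1.5 to <2.0 fold rise, stage 2 for a 2.0 to
#' <3.0 fold rise, stage 3 for >= 3.0 fold or an SCr >= 353.6 umol/L
#' (4.0 mg/dL) during AKI. Urine-output criteria are not used.
#'
#' @param series Data frame or matrix with columns \code{time_hours} and
#'   \code{scr} (umol/L), times strictly increasing.
#' @return List of class \code{aki_status}: \code{has_aki},
#'   \code{stage} (0-3), \code{trigger_time_hours} (NA when no AKI) and
#'   \code{trigger_rule} (\code{"delta48h"}, \code{"fold7d"} or
#'   \code{"none"}).
#' @export
detect_aki <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("time_hours", "scr") %in% names(series))) {
    names(series)[1:2] <- c("time_hours", "scr")
  }
  t <- series$time_hours; s <- series$scr
  if (length(t) < 2L) stop("insufficient SCr data: need at least two measurements")
  if (any(diff(t) <= 0)) stop("SCr series times must be strictly increasing")
  if (any(s <= 0)) stop("SCr values must be positive")

  m <- length(t)
  stage <- 0L
  trigger_time <- Inf
  trigger_rule <- "none"
  max_fold <- -Inf
  for (j in 2:m) {
    prior <- which(t < t[j])
    # absolute-rise clause, 48 h window
    in48 <- prior[t[j] - t[prior] <= KDIGO_DELTA_WINDOW]
    if (length(in48) && any(s[j] - s[in48] >= KDIGO_DELTA_48H)) {
      stage <- max(stage, 1L)
      if (t[j] < trigger_time) { trigger_time <- t[j]; trigger_rule <- "delta48h" }
    }
    # fold clause against the rolling 7-day baseline
    in7d <- prior[t[j] - t[prior] <= KDIGO_FOLD_WINDOW]
    if (length(in7d)) {
      fold <- s[j] / min(s[in7d])
      max_fold <- max(max_fold, fold)
      if (fold >= 1.5 && t[j] < trigger_time) {
        trigger_time <- t[j]; trigger_rule <- "fold7d"
      }
    }
  }
  if (is.finite(max_fold)) {
    if (max_fold >= 3.0) stage <- 3L
    else if (max_fold >= 2.0) stage <- max(stage, 2L)
    else if (max_fold >= 1.5) stage <- max(stage, 1L)
  }
  has_aki <- stage >= 1L
  if (has_aki && max(s) >= KDIGO_ABS_STAGE3) stage <- 3L
  structure(list(has_aki = has_aki,
                 stage = stage,
                 trigger_time_hours = if (has_aki) trigger_time else NA_real_,
                 trigger_rule = if (has_aki) trigger_rule else "none"),
            class = "aki_status")
}

# Band assignment helpers; cutoffs exactly as printed in the cohort
# table (closed/open sides documented in the data dictionary).
band_age <- function(x) cut(floor(x), c(-Inf, 29, 49, 69, Inf),
                            labels = aki_levels$age_band)
band_egfr <- function(x) factor(ifelse(x >= 90, ">=90", ifelse(x >= 60, "60-89", "<=59")),
                                levels = aki_levels$egfr_band)
band_sua <- function(x) factor(ifelse(x < 360, "<=359",
                               ifelse(x < 421, "360-420",
                               ifelse(x < 481, "421-480", ">=481"))),
                               levels = aki_levels$sua_band)
band_sodium <- function(x) factor(ifelse(x < 137, "hypo", ifelse(x > 147, "hyper", "normal")),
                                  levels = aki_levels$sodium_band)
band_potassium <- function(x) factor(ifelse(x < 3.5, "hypo", ifelse(x > 5.3, "hyper", "normal")),
                                     levels = aki_levels$potassium_band)
yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))

#' Discretize eligible patients into the categorical analysis table
#'
#' Applies the published cutoffs (ALT >= 40 U/L, AST >= 35 U/L, TBiL >=
#' 20.4 umol/L, SCr >= 115 umol/L, eGFR bands 90/60, SUA bands
#' 360/421/481, albumin < 35 g/L, hemoglobin < 115 g/L, WBC >= 9.5e9/L,
#' sodium 137-147, potassium 3.5-5.3, age bands 29/50/70) and attaches
#' the KDIGO outcome computed from each patient's SCr series. Missing
#' labs stay missing (\code{NA}); they are never imputed.
#'
#' @param eligible List of patient records (after
#'   \code{\link{apply_eligibility}}).
#' @return A data frame of class \code{coded_cohort}: one row per
#'   patient, all predictors as factors, plus \code{aki} and
#'   \code{aki_stage}.
#' @export
code_cohort <- function(eligible) {
  n <- length(eligible)
  get_lab <- function(name) vapply(eligible, function(p) {
    v <- p$labs[[name]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }, 0)
  labs <- sapply(c("alt", "ast", "tbil", "scr", "egfr", "sua", "albumin",
                   "hemoglobin", "wbc", "sodium", "potassium"),
                 get_lab, simplify = FALSE)
  for (nm in names(labs)) {
    bad <- !is.na(labs[[nm]]) & labs[[nm]] < 0
    if (any(bad)) stop(sprintf("negative %s value for patient(s): %s", nm,
                               paste(which(bad), collapse = ", ")))
  }
  status <- lapply(eligible, function(p) detect_aki(p$scr_series))
  out <- data.frame(
    patient_id = vapply(eligible, `[[`, "", "patient_id"),
    age_band = band_age(vapply(eligible, `[[`, 0, "age_years")),
    gender = factor(vapply(eligible, `[[`, "", "gender"), levels = aki_levels$gender),
    hypertension = yn(vapply(eligible, `[[`, TRUE, "hypertension")),
    diabetes = yn(vapply(eligible, `[[`, TRUE, "diabetes")),
    hm_category = factor(vapply(eligible, `[[`, "", "hm_category"),
                         levels = aki_levels$hm_category),
    admission_type = factor(vapply(eligible, `[[`, "", "admission_type"),
                            levels = aki_levels$admission_type),
    treatment = factor(vapply(eligible, `[[`, "", "treatment"),
                       levels = aki_levels$treatment),
    alt_high = yn(labs$alt >= 40),
    ast_high = yn(labs$ast >= 35),
    tbil_high = yn(labs$tbil >= 20.4),
    scr_high = yn(labs$scr >= 115),
    egfr_band = band_egfr(labs$egfr),
    sua_band = band_sua(labs$sua),
    albumin_low = yn(labs$albumin < 35),
    hemoglobin_low = yn(labs$hemoglobin < 115),
    wbc_high = yn(labs$wbc >= 9.5),
    sodium_band = band_sodium(labs$sodium),
    potassium_band = band_potassium(labs$potassium),
    aki = yn(vapply(status, `[[`, TRUE, "has_aki")),
    aki_stage = vapply(status, `[[`, 0L, "stage"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coded_cohort", "data.frame")
  out
}

#' Data dictionary for the coded analysis table
#'
#' One row per coded variable: level set, reference level, cutoff
#' description, and whether the variable is treated as ordinal in the
#' univariate analysis.
#' @return Data frame.
#' @export
coding_dictionary <- function() {
  reg <- variable_registry()
  data.frame(variable = names(reg),
             levels = vapply(reg, function(v) paste(v$levels, collapse = "|"), ""),
             reference = vapply(reg, `[[`, "", "reference"),
             ordinal = vapply(reg, `[[`, TRUE, "ordinal"),
             description = vapply(reg, `[[`, "", "description"),
             stringsAsFactors = FALSE, row.names = NULL)
}
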