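# Synthetic hematologic-malignancy inpatient cohorts with a known
# ground-truth dependency graph. Marginal frequencies are calibrated to
# the published cohort (n = 2395, 370 AKI episodes); the dependency
# skeleton routes HM category and diabetes through hemoglobin/eGFR into
# AKI, with age and the serum electrolytes as further direct causes.

#' Category level sets of the coded analysis variables
#'
#' Named list of the level sets shared by the cohort generator, the
#' clinical coder and the network code (e.g. \code{aki_levels$egfr_band}
#' is \code{c(">=90", "60-89", "<=59")}).
#' @format Named list of character vectors.
#' @export
aki_levels <- list(
  age_band       = c("<=29", "30-49", "50-69", ">=70"),
  gender         = c("male", "female"),
  hypertension   = c("no", "yes"),
  diabetes       = c("no", "yes"),
  hm_category    = c("lymphoma", "leukemia", "multiple_myeloma"),
  admission_type = c("normal", "emergent"),
  treatment      = c("untreated_palliative", "chemotherapy", "ASCT"),
  alt_high       = c("no", "yes"),
  ast_high       = c("no", "yes"),
  tbil_high      = c("no", "yes"),
  scr_high       = c("no", "yes"),
  sua_band       = c("<=359", "360-420", "421-480", ">=481"),
  albumin_low    = c("no", "yes"),
  wbc_high       = c("no", "yes"),
  sodium_band    = c("hypo", "normal", "hyper"),
  potassium_band = c("hypo", "normal", "hyper"),
  hemoglobin_low = c("no", "yes"),
  egfr_band      = c(">=90", "60-89", "<=59"),
  aki            = c("no", "yes")
)

# Cohort marginal frequencies of the root variables (fractions of the
# published 2395-patient cohort).
default_marginals <- function() {
  list(
    age_band       = c("<=29" = 213, "30-49" = 539, "50-69" = 1236, ">=70" = 407) / 2395,
    gender         = c(male = 1375, female = 1020) / 2395,
    hypertension   = c(no = 2395 - 473, yes = 473) / 2395,
    diabetes       = c(no = 2395 - 814, yes = 814) / 2395,
    hm_category    = c(lymphoma = 1941, leukemia = 201, multiple_myeloma = 253) / 2395,
    admission_type = c(normal = 2232, emergent = 163) / 2395,
    treatment      = c(untreated_palliative = 309, chemotherapy = 2036, ASCT = 50) / 2395,
    alt_high       = c(no = 2395 - 150, yes = 150) / 2395,
    ast_high       = c(no = 2395 - 270, yes = 270) / 2395,
    tbil_high      = c(no = 2395 - 90, yes = 90) / 2395,
    sua_band       = c("<=359" = 1619, "360-420" = 398, "421-480" = 200, ">=481" = 178) / 2395,
    albumin_low    = c(no = 2395 - 584, yes = 584) / 2395,
    wbc_high       = c(no = 2395 - 406, yes = 406) / 2395,
    sodium_band    = c(hypo = 325, normal = 2029, hyper = 41) / 2395,
    potassium_band = c(hypo = 333, normal = 2038, hyper = 24) / 2395
  )
}

#' Default ground-truth generative network
#'
#' Builds the cohort generator's dependency structure: root variables
#' carry the cohort marginal frequencies; hemoglobin depends on HM
#' category, eGFR on HM category and diabetes, and AKI on age, anemia,
#' eGFR band, sodium band and potassium band through a monotone logistic
#' response. The AKI intercept is solved numerically so the implied
#' marginal AKI probability equals \code{target_aki}.
#'
#' @param target_aki Marginal AKI probability (default 0.154, the
#'   published incidence).
#' @param marginal_probs Optional named list overriding root marginals;
#'   each entry must be a probability vector over the variable's levels.
#' @param effects Optional named list overriding the AKI log-odds
#'   effects (\code{age}, \code{hemoglobin}, \code{egfr}, \code{sodium},
#'   \code{potassium}).
#' @return A \code{bn} over the 16 categorical cohort variables plus AKI.
#' @export
default_truth <- function(target_aki = 370 / 2395, marginal_probs = NULL,
                          effects = NULL) {
  lev <- aki_levels
  marg <- default_marginals()
  if (!is.null(marginal_probs)) {
    for (v in names(marginal_probs)) {
      p <- marginal_probs[[v]]
      if (!v %in% names(marg)) stop(sprintf("unknown marginal variable '%s'", v))
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop(sprintf("invalid probability row for variable '%s'", v))
      }
      marg[[v]] <- p
    }
  }

  eff <- list(
    age        = c("<=29" = 1.3, "30-49" = 0, "50-69" = -0.1, ">=70" = 0.7),
    hemoglobin = c(no = 0, yes = 1.5),
    egfr       = c(">=90" = 0, "60-89" = 0.9, "<=59" = 2.8),
    sodium     = c(hypo = 1.9, normal = 0, hyper = 1.7),
    potassium  = c(hypo = 1.7, normal = 0, hyper = 3.3)
  )
  if (!is.null(effects)) eff[names(effects)] <- effects

  # P(anemia | HM): anemia is far more common in leukemia / myeloma
  hb_prob <- rbind(lymphoma = c(no = 0.50, yes = 0.50),
                   leukemia = c(no = 0.20, yes = 0.80),
                   multiple_myeloma = c(no = 0.22, yes = 0.78))
  # P(eGFR band | HM, diabetes); rows in expand.grid order (HM fastest)
  egfr_prob <- rbind(
    c(0.78, 0.19, 0.03),  # lymphoma, no
    c(0.60, 0.32, 0.08),  # leukemia, no
    c(0.50, 0.38, 0.12),  # myeloma,  no
    c(0.62, 0.30, 0.08),  # lymphoma, diabetic
    c(0.45, 0.40, 0.15),  # leukemia, diabetic
    c(0.35, 0.45, 0.20))  # myeloma,  diabetic

  # joint parent distribution of the AKI family
  p_hm <- marg$hm_category; p_db <- marg$diabetes
  hb_egfr <- matrix(0, 2, 3, dimnames = list(lev$hemoglobin_low, lev$egfr_band))
  for (h in 1:3) for (d in 1:2) {
    w <- p_hm[[h]] * p_db[[d]]
    cfg <- (d - 1L) * 3L + h
    hb_egfr <- hb_egfr + w * outer(hb_prob[h, ], egfr_prob[cfg, ])
  }

  grid <- expand.grid(age_band = lev$age_band, hemoglobin_low = lev$hemoglobin_low,
                      egfr_band = lev$egfr_band, sodium_band = lev$sodium_band,
                      potassium_band = lev$potassium_band, stringsAsFactors = FALSE)
  lp0 <- eff$age[grid$age_band] + eff$hemoglobin[grid$hemoglobin_low] +
    eff$egfr[grid$egfr_band] + eff$sodium[grid$sodium_band] +
    eff$potassium[grid$potassium_band]
  wt <- marg$age_band[grid$age_band] *
    hb_egfr[cbind(grid$hemoglobin_low, grid$egfr_band)] *
    marg$sodium_band[grid$sodium_band] * marg$potassium_band[grid$potassium_band]
  b0 <- stats::uniroot(function(b) sum(wt * stats::plogis(b + lp0)) - target_aki,
                       c(-12, 4), tol = 1e-10)$root
  p_aki <- stats::plogis(b0 + lp0)

  nodes <- names(lev)[names(lev) != "scr_high"]
  arcs <- rbind(c("hm_category", "hemoglobin_low"),
                c("hm_category", "egfr_band"),
                c("diabetes", "egfr_band"),
                c("age_band", "aki"),
                c("hemoglobin_low", "aki"),
                c("egfr_band", "aki"),
                c("sodium_band", "aki"),
                c("potassium_band", "aki"))
  dag <- bn_dag(nodes, arcs)

  cpts <- list()
  for (v in setdiff(nodes, c("hemoglobin_low", "egfr_band", "aki"))) {
    cpts[[v]] <- bn_cpt(v, lev[[v]], prob = marg[[v]])
  }
  cpts$hemoglobin_low <- bn_cpt("hemoglobin_low", lev$hemoglobin_low,
                                "hm_category", lev, hb_prob)
  cpts$egfr_band <- bn_cpt("egfr_band", lev$egfr_band,
                           c("hm_category", "diabetes"), lev, egfr_prob)
  cpts$aki <- bn_cpt("aki", lev$aki,
                     c("age_band", "hemoglobin_low", "egfr_band",
                       "sodium_band", "potassium_band"), lev,
                     cbind(no = 1 - p_aki, yes = p_aki))
  bayes_net(dag, cpts)
}

#' Parameters of the synthetic cohort generator
#'
#' The defaults are the study conditions the package is exercised under:
#' cohort size 2395, marginals from the published Table, AKI stage mix
#' 308/41/21, serum creatinine baselines uniform on 40-120 umol/L, and
#' AKI trajectories that multiply baseline by a stage-specific fold
#' factor inside a 48-hour window.
#'
#' @param n_patients Cohort size.
#' @param seed RNG seed (may be overridden in \code{simulate_cohort}).
#' @param truth Ground-truth \code{bn}; default \code{default_truth()}.
#' @param marginal_probs Optional root-marginal overrides, passed to
#'   \code{\link{default_truth}} when \code{truth} is not supplied.
#' @param scr_baseline_range Baseline SCr interval, umol/L.
#' @param aki_stage_probs Probabilities of stage 1/2/3 given AKI.
#' @param aki_fold_ranges List of per-stage fold-change intervals.
#' @param lab_missing_rate Missing-at-random masking rate for admission
#'   labs (0 disables; SCr series are never masked).
#' @param exclusion_rates Rates of injected ineligible patients
#'   (\code{short_stay}, \code{baseline_rrt}, \code{single_scr}).
#' @return Object of class \code{cohort_params}.
#' @export
cohort_params <- function(n_patients = 2395L, seed = 1L, truth = NULL,
                          marginal_probs = NULL,
                          scr_baseline_range = c(40, 120),
                          aki_stage_probs = c(308, 41, 21) / 370,
                          aki_fold_ranges = list(c(1.55, 1.95), c(2.05, 2.85), c(3.05, 3.90)),
                          lab_missing_rate = 0,
                          exclusion_rates = c(short_stay = 0, baseline_rrt = 0, single_scr = 0)) {
  stopifnot(n_patients >= 0, length(scr_baseline_range) == 2,
            scr_baseline_range[1] > 0, diff(scr_baseline_range) > 0,
            lab_missing_rate >= 0, lab_missing_rate < 1)
  check_prob_row(aki_stage_probs, "aki_stage_probs")
  if (is.null(truth)) truth <- default_truth(marginal_probs = marginal_probs)
  stopifnot(inherits(truth, "bn"))
  exc <- c(short_stay = 0, baseline_rrt = 0, single_scr = 0)
  exc[names(exclusion_rates)] <- exclusion_rates
  structure(list(n_patients = as.integer(n_patients), seed = seed, truth = truth,
                 scr_baseline_range = scr_baseline_range,
                 aki_stage_probs = aki_stage_probs,
                 aki_fold_ranges = aki_fold_ranges,
                 lab_missing_rate = lab_missing_rate,
                 exclusion_rates = exc),
            class = "cohort_params")
}

# Continuous value ranges backing each category band (units as in the
# admission-lab panel; uniform draws within band).
band_ranges <- list(
  alt_high       = list(no = c(5, 39.9), yes = c(40, 200)),          # U/L
  ast_high       = list(no = c(8, 34.9), yes = c(35, 180)),          # U/L
  tbil_high      = list(no = c(3, 20.3), yes = c(20.5, 80)),         # umol/L
  sua_band       = list("<=359" = c(120, 359), "360-420" = c(360, 420.9),
                        "421-480" = c(421, 480.9), ">=481" = c(481, 900)),
  albumin_low    = list(no = c(35, 52), yes = c(20, 34.9)),          # g/L
  wbc_high       = list(no = c(1.5, 9.4), yes = c(9.5, 60)),         # 1e9/L
  sodium_band    = list(hypo = c(118, 136.9), normal = c(137, 147), hyper = c(147.1, 162)),
  potassium_band = list(hypo = c(2.4, 3.49), normal = c(3.5, 5.3), hyper = c(5.31, 7.2)),
  hemoglobin_low = list(no = c(115, 165), yes = c(55, 114.9)),       # g/L
  egfr_band      = list(">=90" = c(90, 130), "60-89" = c(60, 89.9), "<=59" = c(8, 59.9)),
  age_band       = list("<=29" = c(16, 29.9), "30-49" = c(30, 49.9),
                        "50-69" = c(50, 69.9), ">=70" = c(70, 92))
)

draw_in_band <- function(band, var) {
  r <- band_ranges[[var]][as.character(band)]
  lo <- vapply(r, `[`, 0, 1); hi <- vapply(r, `[`, 0, 2)
  stats::runif(length(band), lo, hi)
}

#' Simulate a synthetic HM inpatient cohort
#'
#' Samples the categorical ground truth from the generator's network,
#' then materializes patient records: continuous admission labs drawn
#' uniformly within the sampled band, and a serum-creatinine series that
#' meets the KDIGO criteria exactly for the patients whose sampled AKI
#' indicator is positive (fold rise to the stage-specific multiple
#' within 48 h) and for no others (jitter within +/- 9% of baseline).
#'
#' @param params A \code{\link{cohort_params}} object.
#' @param seed Optional override of \code{params$seed}.
#' @return Object of class \code{aki_cohort}: a list of patient records,
#'   with the sampled categorical truth in \code{attr(, "truth")}.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(seed)) seed <- params$seed
  n <- params$n_patients
  if (n == 0L) {
    return(structure(list(), class = "aki_cohort",
                     truth = data.frame(), params = params))
  }
  with_seed(seed, {
    truth <- rbn(params$truth, n)
    aki <- truth$aki == "yes"
    stage <- integer(n)
    stage[aki] <- sample.int(3L, sum(aki), replace = TRUE, prob = params$aki_stage_probs)
    truth$aki_stage <- stage

    age <- draw_in_band(truth$age_band, "age_band")
    labs <- data.frame(
      alt = draw_in_band(truth$alt_high, "alt_high"),
      ast = draw_in_band(truth$ast_high, "ast_high"),
      tbil = draw_in_band(truth$tbil_high, "tbil_high"),
      egfr = draw_in_band(truth$egfr_band, "egfr_band"),
      sua = draw_in_band(truth$sua_band, "sua_band"),
      albumin = draw_in_band(truth$albumin_low, "albumin_low"),
      hemoglobin = draw_in_band(truth$hemoglobin_low, "hemoglobin_low"),
      wbc = draw_in_band(truth$wbc_high, "wbc_high"),
      sodium = draw_in_band(truth$sodium_band, "sodium_band"),
      potassium = draw_in_band(truth$potassium_band, "potassium_band")
    )
    baseline <- stats::runif(n, params$scr_baseline_range[1], params$scr_baseline_range[2])
    labs$scr <- baseline

    if (params$lab_missing_rate > 0) {
      mask <- matrix(stats::runif(n * ncol(labs)) < params$lab_missing_rate,
                     n, ncol(labs))
      mask[, which(names(labs) == "scr")] <- FALSE  # series stays intact
      labs[mask] <- NA_real_
    }

    exc <- params$exclusion_rates
    u <- stats::runif(n)
    flag_short <- u < exc[["short_stay"]]
    flag_rrt <- !flag_short & u < exc[["short_stay"]] + exc[["baseline_rrt"]]
    flag_single <- !flag_short & !flag_rrt &
      u < exc[["short_stay"]] + exc[["baseline_rrt"]] + exc[["single_scr"]]

    los <- stats::runif(n, 96, 800)
    los[flag_short] <- stats::runif(sum(flag_short), 4, 23)

    records <- vector("list", n)
    for (i in seq_len(n)) {
      b <- baseline[i]
      if (flag_single[i]) {
        series <- data.frame(time_hours = 0, scr = b)
      } else if (aki[i] && !flag_short[i]) {
        fr <- params$aki_fold_ranges[[stage[i]]]
        mult <- stats::runif(1, fr[1], fr[2])
        times <- c(0, 30, 66, 110)
        vals <- c(b, b * (1 + stats::runif(1, 0, 0.05)), b * mult,
                  b * mult * (1 - stats::runif(1, 0, 0.10)))
        series <- data.frame(time_hours = times, scr = vals)
      } else {
        times <- cumsum(c(0, stats::runif(3, 40, 56)))
        vals <- b * c(1, 1 + stats::runif(3, -0.09, 0.09))
        series <- data.frame(time_hours = times, scr = vals)
      }
      lab_i <- as.list(labs[i, ])
      records[[i]] <- structure(list(
        patient_id = sprintf("P%05d", i),
        age_years = age[i],
        gender = as.character(truth$gender[i]),
        hypertension = truth$hypertension[i] == "yes",
        diabetes = truth$diabetes[i] == "yes",
        hm_category = as.character(truth$hm_category[i]),
        admission_type = as.character(truth$admission_type[i]),
        treatment = as.character(truth$treatment[i]),
        dialysis_or_rrt_at_baseline = flag_rrt[i],
        labs = lab_i,
        scr_series = series,
        los_hours = los[i]
      ), class = "patient_record")
    }
    structure(records, class = "aki_cohort", truth = truth, params = params)
  })
}

#' @export
print.aki_cohort <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("Synthetic HM cohort: %d patients", length(x)))
  if (NROW(tr)) cat(sprintf(", %d (%.1f%%) AKI-destined", sum(tr$aki == "yes"),
                            100 * mean(tr$aki == "yes")))
  cat("\n")
  invisible(x)
}
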