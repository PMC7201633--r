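# Eligibility filters, KDIGO detection/staging, discretization cutoffs.

test_that("eligibility filters exclude by the fixed reasons in order", {
  base <- simulate_cohort(cohort_params(n_patients = 5), seed = 2)
  p_short <- base[[1]]; p_short$los_hours <- 20
  p_rrt <- base[[2]]; p_rrt$dialysis_or_rrt_at_baseline <- TRUE
  p_single <- base[[3]]; p_single$scr_series <- p_single$scr_series[1, , drop = FALSE]
  # short stay takes precedence over the RRT flag
  p_both <- base[[4]]; p_both$los_hours <- 10; p_both$dialysis_or_rrt_at_baseline <- TRUE
  res <- apply_eligibility(list(p_short, p_rrt, p_single, p_both, base[[5]]))
  expect_identical(res$exclusion_log,
                   c(los_lt_24h = 2L, baseline_rrt = 1L, insufficient_scr = 1L))
  expect_length(res$eligible, 1)
  all_ok <- apply_eligibility(base)
  expect_identical(unname(all_ok$exclusion_log), c(0L, 0L, 0L))
})

test_that("detect_aki reproduces the KDIGO worked examples", {
  s1 <- detect_aki(data.frame(time_hours = c(0, 24), scr = c(60, 95)))
  expect_true(s1$has_aki); expect_equal(s1$stage, 1L)  # 95/60 = 1.58-fold
  # both clauses fire here (delta 35 >= 26.5); the absolute-rise clause
  # is reported at ties
  expect_equal(s1$trigger_rule, "delta48h"); expect_equal(s1$trigger_time_hours, 24)

  # fold clause alone: delta 26 < 26.5 but 76/50 = 1.52-fold
  sf <- detect_aki(data.frame(time_hours = c(0, 24), scr = c(50, 76)))
  expect_equal(sf$stage, 1L); expect_equal(sf$trigger_rule, "fold7d")

  s0 <- detect_aki(data.frame(time_hours = c(0, 48, 96), scr = c(80, 80, 80)))
  expect_false(s0$has_aki); expect_equal(s0$stage, 0L)
  expect_equal(s0$trigger_rule, "none"); expect_true(is.na(s0$trigger_time_hours))

  s3 <- detect_aki(data.frame(time_hours = c(0, 72), scr = c(70, 215)))
  expect_equal(s3$stage, 3L)  # 3.07-fold

  # absolute-rise clause alone (delta 28 over 40 h, fold 1.28)
  sd <- detect_aki(data.frame(time_hours = c(0, 40), scr = c(100, 128)))
  expect_equal(sd$stage, 1L); expect_equal(sd$trigger_rule, "delta48h")

  # stage 2 band: 2.0- to <3.0-fold
  s2 <- detect_aki(data.frame(time_hours = c(0, 100), scr = c(60, 150)))
  expect_equal(s2$stage, 2L)

  # absolute stage-3 threshold (353.6 umol/L) during AKI
  sa <- detect_aki(data.frame(time_hours = c(0, 30), scr = c(200, 360)))
  expect_equal(sa$stage, 3L)

  expect_error(detect_aki(data.frame(time_hours = 0, scr = 80)), "insufficient SCr")
  expect_error(detect_aki(data.frame(time_hours = c(0, 0), scr = c(80, 90))),
               "strictly increasing")
})

test_that("detect_aki agrees with the exhaustive pairwise oracle", {
  for (s in 1:300) {
    ser <- rand_scr_series(s)
    got <- detect_aki(ser)
    want <- oracle_detect_aki(ser)
    expect_identical(got$has_aki, want$has_aki, label = sprintf("series %d aki", s))
    expect_identical(got$stage, want$stage, label = sprintf("series %d stage", s))
  }
})

test_that("discretization respects the printed cutoffs and boundary sides", {
  rec <- function(labs, age = 55) structure(list(
    patient_id = "T", age_years = age, gender = "male", hypertension = FALSE,
    diabetes = FALSE, hm_category = "lymphoma", admission_type = "normal",
    treatment = "chemotherapy", dialysis_or_rrt_at_baseline = FALSE,
    labs = labs, scr_series = data.frame(time_hours = c(0, 48), scr = c(80, 80)),
    los_hours = 100), class = "patient_record")
  base <- list(alt = 20, ast = 20, tbil = 10, scr = 80, egfr = 95, sua = 300,
               albumin = 40, hemoglobin = 130, wbc = 6, sodium = 140, potassium = 4)
  variants <- list(
    rec(modifyList(base, list(sodium = 135))),
    rec(modifyList(base, list(sodium = 136.5))),
    rec(modifyList(base, list(egfr = 90))),
    rec(modifyList(base, list(hemoglobin = 115))),
    rec(modifyList(base, list(hemoglobin = 114.9))),
    rec(base, age = 29.6),
    rec(base, age = 70),
    rec(modifyList(base, list(tbil = 20.4))),
    rec(modifyList(base, list(potassium = 5.31))),
    rec(modifyList(base, list(sua = 421)))
  )
  cd <- code_cohort(variants)
  expect_equal(as.character(cd$sodium_band[1:2]), c("hypo", "hypo"))
  expect_equal(as.character(cd$egfr_band[3]), ">=90")
  expect_equal(as.character(cd$hemoglobin_low[4:5]), c("no", "yes"))
  expect_equal(as.character(cd$age_band[6:7]), c("<=29", ">=70"))
  expect_equal(as.character(cd$tbil_high[8]), "yes")
  expect_equal(as.character(cd$potassium_band[9]), "hyper")
  expect_equal(as.character(cd$sua_band[10]), "421-480")

  # missing lab stays missing
  miss <- rec(modifyList(base, list(sodium = NA_real_)))
  expect_true(is.na(code_cohort(list(miss))$sodium_band))
  # negative value rejected
  neg <- rec(modifyList(base, list(albumin = -1)))
  expect_error(code_cohort(list(neg)), "negative")
})

test_that("coding is total and the coded AKI rate tracks the generator target", {
  fx <- coded_cohort_fixture(2000, 31)
  expect_equal(nrow(fx$coded), 2000)
  expect_false(any(duplicated(fx$coded$patient_id)))
  expect_lt(abs(mean(fx$coded$aki == "yes") - 370 / 2395), 0.02)
})
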