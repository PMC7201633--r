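# Grouped design construction and the group-LASSO path: analytic
# anchors, group sparsity, information-criterion and CV selection.

test_that("build_design expands dummies with one group per predictor", {
  fx <- coded_cohort_fixture(800, 17)
  d <- build_design(fx$coded, c("egfr_band", "diabetes"))
  expect_equal(sum(d$group == "egfr_band"), 2L)
  expect_equal(sum(d$group == "diabetes"), 1L)
  d_all <- build_design(fx$coded)
  expect_equal(length(unique(d_all$group)), length(d_all$predictors))
  tab <- table(d_all$group)
  want <- vapply(names(tab), function(v)
    nlevels(droplevels(fx$coded[[v]])) - 1L, 1L)
  expect_equal(as.integer(tab), unname(want))

  one <- fx$coded; one$gender <- factor("male", levels = c("male", "female"))
  class(one) <- class(fx$coded)
  expect_error(build_design(one, c("gender", "diabetes")), "single observed level")

  holes <- fx$coded; holes$sodium_band[1:25] <- NA
  class(holes) <- class(fx$coded)
  expect_message(d2 <- build_design(holes, c("sodium_band", "diabetes")), "dropped 25")
  expect_equal(nrow(d2$X), nrow(fx$coded) - 25)
})

test_that("gaussian single-group fit matches the closed-form soft threshold", {
  withr::with_seed(3, {
    n <- 200
    Z <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z)) * sqrt(n)  # centered columns with Q'Q = n I
    y <- as.vector(Q %*% c(0.8, -0.4, 0.2) + rnorm(n, 0, 0.3))
    design <- structure(list(X = Q, y = y, group = rep("g", 3),
                             predictors = "g", references = c(g = "ref"),
                             n_dropped = 0L), class = "grouped_design")
    for (lam in c(0.05, 0.2, 0.5)) {
      fit <- fit_path(design, lambda = lam, family = "gaussian", tol = 1e-12)
      u <- as.vector(crossprod(Q, y - mean(y))) / n
      gamma_star <- max(0, 1 - lam / sqrt(sum(u^2))) * u
      # design columns are already orthonormalized, so back-transform is identity-like
      beta_star <- gamma_star
      expect_equal(unname(fit$beta[, 1]), beta_star, tolerance = 1e-8,
                   label = sprintf("lambda %.2f", lam))
    }
  })
})

test_that("the largest lambda yields the null model with prevalence intercept", {
  fx <- coded_cohort_fixture(800, 17)
  d <- build_design(fx$coded, c("egfr_band", "sodium_band", "hemoglobin_low"))
  path <- fit_path(d, nlambda = 20)
  expect_true(all(abs(path$beta[, 1]) < 1e-10))
  expect_equal(path$intercept[1], qlogis(mean(d$y)), tolerance = 1e-6)
  expect_equal(path$df[1], 1L)
})

test_that("group sparsity holds at every path point and deviance is monotone", {
  fx <- coded_cohort_fixture(800, 17)
  d <- build_design(fx$coded, c("egfr_band", "sua_band", "age_band", "diabetes"))
  path <- fit_path(d, nlambda = 25)
  for (k in seq_along(path$lambda)) {
    for (g in unique(d$group)) {
      b <- path$beta[d$group == g, k]
      expect_true(all(abs(b) > 1e-10) || all(abs(b) <= 1e-10),
                  label = sprintf("group %s at lambda %d", g, k))
    }
  }
  expect_true(all(diff(path$deviance) <= 1e-6))
})

test_that("lambda = 0 recovers the unpenalized logistic MLE", {
  fx <- coded_cohort_fixture(1500, 11)
  d <- build_design(fx$coded, c("egfr_band", "sodium_band", "hemoglobin_low",
                                "age_band", "potassium_band"))
  fit <- fit_path(d, lambda = c(1e-3, 0), tol = 1e-9)
  g <- stats::glm(d$y ~ d$X, family = stats::binomial())
  expect_lt(max(abs(unname(coef(g)[-1]) - unname(fit$beta[, 2]))), 1e-4)
  expect_lt(abs(unname(coef(g)[1]) - fit$intercept[2]), 1e-4)
})

test_that("select_ic minimizes its criterion; BIC never exceeds AIC in density", {
  fx <- coded_cohort_fixture(1500, 11)
  d <- build_design(fx$coded)
  path <- fit_path(d, nlambda = 40)
  sel1 <- select_ic(path, "BIC")
  expect_equal(sel1$value, min(path$bic))
  single <- fit_path(d, lambda = path$lambda[10])
  expect_equal(select_ic(single, "BIC")$lambda, path$lambda[10])

  sel_a <- select_ic(path, "AIC")
  expect_true(all(sel1$groups %in% sel_a$groups))
  sel_g <- select_ic(path, "GCV")
  expect_equal(sel_g$value, min(path$gcv))
})

test_that("cross-validated lambda.min is reproducible and ignores permuted outcomes", {
  fx <- coded_cohort_fixture(800, 17)
  d <- build_design(fx$coded, c("egfr_band", "sodium_band", "hemoglobin_low",
                                "potassium_band", "wbc_high", "treatment"))
  cv1 <- cv_lambda(d, k = 5, seed = 42, nlambda = 25)
  cv2 <- cv_lambda(d, k = 5, seed = 42, nlambda = 25)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$cv_error, cv2$cv_error)
  expect_true(cv1$lambda_min %in% cv1$lambda)
  fold_sizes <- table(cv1$fold_assignments)
  expect_lte(max(fold_sizes) - min(fold_sizes), 2)

  # outcome carries no signal after permutation: selection collapses
  near_empty <- 0L
  for (s in 1:20) {
    dperm <- d
    dperm$y <- withr::with_seed(100 + s, sample(d$y))
    sel <- select_ic(fit_path(dperm, nlambda = 20, lambda_min_ratio = 0.05), "BIC")
    if (length(sel$groups) <= 1L) near_empty <- near_empty + 1L
  }
  expect_gte(near_empty, 18L)
})
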