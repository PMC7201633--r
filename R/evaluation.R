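# Predictive evaluation: posterior AKI scores from the network, ROC /
# AUC with DeLong intervals, an unpenalized logistic baseline, and
# stratified k-fold cross-validation of the whole selection ->
# structure -> parameters pipeline.

#' Posterior P(AKI = yes) for coded rows
#'
#' Each row's observed predictor levels (any subset may be missing)
#' become evidence; the query node is never used as evidence. Exact
#' enumeration is used when the network's state space allows it,
#' likelihood weighting otherwise. Posteriors are cached per unique
#' evidence configuration.
#'
#' @param net A \code{bn}.
#' @param newdata Data frame of coded rows.
#' @param query Outcome node (default \code{"aki"}).
#' @param level Level scored (default \code{"yes"}).
#' @param n_samples,seed Likelihood-weighting controls (used only when
#'   enumeration is infeasible).
#' @return Numeric vector of posterior probabilities.
#' @export
predict_bn <- function(net, newdata, query = "aki", level = "yes",
                       n_samples = 20000L, seed = 1L) {
  ev_nodes <- setdiff(intersect(net$dag$nodes, names(newdata)), query)
  lev <- bn_levels(net)
  exact_ok <- prod(vapply(lev, length, 1L)) <= 2^20
  joint <- if (exact_ok) joint_enumeration(net) else NULL
  keys <- apply(newdata[, ev_nodes, drop = FALSE], 1L, function(r) {
    paste(ifelse(is.na(r), ".", as.character(r)), collapse = "|")
  })
  out <- numeric(nrow(newdata))
  for (key in unique(keys)) {
    i <- which(keys == key)[1L]
    ev <- list()
    for (nd in ev_nodes) {
      val <- newdata[[nd]][i]
      if (!is.na(val)) ev[[nd]] <- as.character(val)
    }
    p <- if (exact_ok) infer_exact(net, ev, query, joint = joint)[[level]]
    else infer_lw(net, ev, query, n_samples = n_samples, seed = seed)$prob[[level]]
    out[keys == key] <- p
  }
  out
}

#' ROC curve and AUC with confidence interval
#'
#' The AUC is the tie-corrected Mann-Whitney concordance (equivalent to
#' the trapezoidal area); the interval is DeLong's by default, or a
#' seeded bootstrap percentile interval.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (logical, 0/1, or factor whose second
#'   level is the event).
#' @param conf_level Confidence level.
#' @param ci_method \code{"delong"} (default) or \code{"bootstrap"}.
#' @param boot_reps,seed Bootstrap controls.
#' @return Object of class \code{roc_result}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, and the ROC points (\code{thresholds},
#'   \code{sensitivity}, \code{specificity}).
#' @export
auc <- function(scores, labels, conf_level = 0.95,
                ci_method = c("delong", "bootstrap"),
                boot_reps = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both outcome classes must be present")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  # Mann-Whitney with half credit for ties, via midranks
  r <- rank(c(pos, neg), ties.method = "average")
  a <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  roc_obj <- pROC::roc(response = labels, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- tryCatch({
    if (ci_method == "delong") {
      as.numeric(pROC::ci.auc(roc_obj, conf.level = conf_level, method = "delong"))
    } else {
      with_seed(seed, as.numeric(pROC::ci.auc(
        roc_obj, conf.level = conf_level, method = "bootstrap",
        boot.n = boot_reps, progress = "none")))
    }
  }, error = function(e) c(a, a, a))  # degenerate scores: zero-width interval
  if (anyNA(ci)) ci <- c(a, a, a)
  structure(list(auc = a,
                 ci_low = max(0, min(ci[1], a)), ci_high = min(1, max(ci[3], a)),
                 conf_level = conf_level, ci_method = ci_method,
                 thresholds = roc_obj$thresholds,
                 sensitivity = roc_obj$sensitivities,
                 specificity = roc_obj$specificities),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f, %s)\n", x$auc,
              round(100 * x$conf_level), x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

#' Unpenalized logistic score model on selected predictors
#'
#' The conventional baseline: a multivariable logistic regression on the
#' (group-LASSO selected) predictors, scored by fitted probability.
#' Complete cases only. Apparent separation triggers a warning and a
#' ridge refit with a tiny penalty.
#'
#' @param coded A \code{coded_cohort}.
#' @param predictors Predictor columns.
#' @param outcome Outcome column (default \code{"aki"}).
#' @return List of class \code{logistic_baseline}: \code{model} (glm or
#'   ridge coefficients), \code{scores}, \code{labels}, \code{roc}.
#' @export
logistic_baseline <- function(coded, predictors, outcome = "aki") {
  df <- coded[, c(predictors, outcome), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L else y <- as.integer(as.logical(y))
  ridge <- FALSE
  if (length(predictors)) {
    fml <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, data = cbind(df, y = y), family = stats::binomial()))
    if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      warning("apparent separation in logistic baseline; refitting with a tiny ridge penalty")
      ridge <- TRUE
      mm <- stats::model.matrix(fml, data = cbind(df, y = y))[, -1, drop = FALSE]
      rfit <- glmnet::glmnet(mm, y, family = "binomial", alpha = 0, lambda = 1e-6)
      scores <- as.vector(stats::predict(rfit, mm, type = "response"))
      fit <- rfit
    }
    if (!ridge) scores <- stats::fitted(fit)
  } else {
    fit <- NULL
    scores <- rep(mean(y), length(y))
  }
  roc <- if (length(unique(y)) > 1L) auc(scores, y) else NULL
  structure(list(model = fit, ridge = ridge, scores = scores, labels = y, roc = roc),
            class = "logistic_baseline")
}

#' Stratified folds preserving outcome prevalence
#' @noRd
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
}

#' Cross-validate the full selection -> network -> prediction pipeline
#'
#' Per fold, variable selection (group LASSO, BIC), structure learning
#' (tabu/BIC) and CPT fitting are re-run on the training rows only;
#' held-out rows are scored by the fold's network and pooled into one
#' ROC. Folds are stratified on the outcome. The comparison p-value
#' against the full-data fit is a chi-square on correct/incorrect
#' classification counts at each fit's Youden-optimal threshold (an
#' interpretation of the accuracy comparison, labeled as such).
#'
#' @param coded A \code{coded_cohort}.
#' @param k Folds (default 10).
#' @param seed RNG seed (fold assignment + per-fold learning).
#' @param predictors Candidate predictors (default: registry variables).
#' @param smoothing CPT pseudo-count used in per-fold fits.
#' @param full_scores Optional full-data scores to compare against (with
#'   labels matching \code{coded}).
#' @return Object of class \code{cv_report}: \code{fold_auc},
#'   \code{pooled} (a \code{roc_result}), \code{accuracy_p_value}
#'   (NA without \code{full_scores}), \code{fold_assignments}.
#' @export
crossvalidate <- function(coded, k = 10L, seed = 1L, predictors = NULL,
                          smoothing = 1, full_scores = NULL) {
  stopifnot(k >= 2L)
  if (is.null(predictors)) predictors <- intersect(names(variable_registry()), names(coded))
  y <- as.integer(coded$aki == "yes")
  folds <- stratified_folds(y, k, stage_seed(seed, 71L))
  scores <- rep(NA_real_, nrow(coded))
  fold_auc <- numeric(k)
  for (fold in seq_len(k)) {
    test <- folds == fold
    train <- coded[!test, , drop = FALSE]
    class(train) <- class(coded)
    design <- build_design(train, predictors)
    sel <- select_ic(fit_path(design, nlambda = 50L), "BIC")
    nodes <- union(sel$groups, "aki")
    if (length(nodes) < 2L) nodes <- union(nodes, predictors[1])
    dag <- tabu_learn(train, nodes = nodes)
    net <- suppressWarnings(fit_cpts(dag, train, smoothing = smoothing,
                                     levels = aki_levels[nodes]))
    scores[test] <- predict_bn(net, coded[test, , drop = FALSE],
                               seed = stage_seed(seed, 100L + fold))
    fold_auc[fold] <- if (length(unique(y[test])) > 1L) auc(scores[test], y[test])$auc else NA_real_
  }
  pooled <- auc(scores, y)
  acc_p <- NA_real_
  if (!is.null(full_scores)) {
    acc <- function(s) {
      # Youden-optimal threshold accuracy
      thr <- youden_threshold(s, y)
      mean((s >= thr) == (y == 1L))
    }
    n_cv <- round(acc(scores) * length(y)); n_full <- round(acc(full_scores) * length(y))
    tab <- rbind(c(n_full, length(y) - n_full), c(n_cv, length(y) - n_cv))
    acc_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  structure(list(fold_auc = fold_auc, pooled = pooled,
                 accuracy_p_value = acc_p, fold_assignments = folds),
            class = "cv_report")
}

#' Youden-optimal classification threshold
#' @noRd
youden_threshold <- function(scores, y) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sens <- mean(scores[y == 1L] >= t)
    spec <- mean(scores[y == 0L] < t)
    sens + spec - 1
  }, 0)
  thr[which.max(j)]
}
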