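# Group-LASSO penalized logistic regression over grouped dummy
# variables: dummy expansion with a group map, a lambda path fitted by
# block coordinate descent with group-wise soft-thresholding on
# within-group orthonormalized predictors, information-criterion
# selection, and k-fold cross-validated lambda.min.
#
# Objective: (1/n) * loss(beta) + lambda * sum_j m_j ||beta_j||,
# with loss the binomial negative log-likelihood (or squared error /2
# for the gaussian family) and m_j the group multiplier (1 by default).

#' Dummy-expanded grouped design matrix
#'
#' Decomposes each categorical predictor into indicator columns for its
#' non-reference levels and records the column-to-group map. Rows with a
#' missing predictor or outcome are dropped (count kept in the result).
#'
#' @param coded A \code{coded_cohort} (or any data frame with factor
#'   predictors and an outcome column).
#' @param predictors Character vector of predictor columns; defaults to
#'   every registry variable present.
#' @param outcome Outcome column (default \code{"aki"}); must be binary.
#' @return Object of class \code{grouped_design}: \code{X}, \code{y}
#'   (0/1), \code{group} (character per column), \code{predictors},
#'   \code{references}, \code{n_dropped}.
#' @export
build_design <- function(coded, predictors = NULL, outcome = "aki") {
  reg <- variable_registry()
  if (is.null(predictors)) predictors <- intersect(names(reg), names(coded))
  miss <- setdiff(c(predictors, outcome), names(coded))
  if (length(miss)) stop(sprintf("column(s) not in data: %s", paste(miss, collapse = ", ")))
  df <- coded[, c(predictors, outcome), drop = FALSE]
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped) message(sprintf("build_design: dropped %d row(s) with missing values", n_dropped))
  df <- df[keep, , drop = FALSE]

  cols <- list(); group <- character(0); refs <- character(0)
  for (v in predictors) {
    x <- df[[v]]
    if (!is.factor(x)) x <- factor(x)
    x <- droplevels(x)
    lev <- levels(x)
    if (length(lev) < 2L) stop(sprintf("predictor '%s' has a single observed level", v))
    ref <- if (!is.null(reg[[v]]) && reg[[v]]$reference %in% lev) reg[[v]]$reference else lev[1]
    refs[v] <- ref
    for (l in setdiff(lev, ref)) {
      cols[[paste(v, l, sep = "=")]] <- as.numeric(x == l)
      group <- c(group, v)
    }
  }
  X <- do.call(cbind, cols)
  y <- df[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L else y <- as.integer(as.logical(y))
  if (!all(y %in% 0:1)) stop("outcome must be binary")
  structure(list(X = X, y = y, group = group, predictors = predictors,
                 references = refs, n_dropped = n_dropped),
            class = "grouped_design")
}

#' Within-group orthonormalization (internal)
#'
#' Centers the design and decomposes each group so Q_j' Q_j = n I;
#' returns the back-transform matrices.
#' @noRd
orthonormalize_design <- function(design) {
  X <- design$X; n <- nrow(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers)
  groups <- unique(design$group)
  Q <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  back <- list()  # beta_j = back[[j]] %*% gamma_j
  for (g in groups) {
    jj <- which(design$group == g)
    sv <- svd(Xc[, jj, drop = FALSE])
    if (any(sv$d < 1e-10 * max(sv$d, 1e-300))) {
      stop(sprintf("group '%s' is rank-deficient after centering", g))
    }
    Q[, jj] <- sv$u * sqrt(n)
    back[[g]] <- sv$v %*% diag(sqrt(n) / sv$d, length(jj))
  }
  list(Q = Q, back = back, centers = centers, groups = groups)
}

#' Fit a group-LASSO regularization path
#'
#' Block coordinate descent with group-wise soft-thresholding. For the
#' binomial family the logistic loss is majorized by its curvature
#' bound 1/4, giving the update
#' \eqn{\gamma_j \leftarrow (1 - \lambda m_j / (v \|u_j\|))_+ u_j} with
#' \eqn{u_j = \gamma_j + Q_j' (y - p) / (v n)} and \eqn{v = 1/4}; for
#' the gaussian family the blockwise update is exact (\eqn{v = 1}).
#' Coefficients are reported on the original dummy scale
#' (back-transformed from the orthonormalized fit).
#'
#' @param design A \code{grouped_design}.
#' @param lambda Optional decreasing penalty sequence; by default
#'   \code{nlambda} log-spaced values from \eqn{\lambda_{max}} (the
#'   smallest value with all groups at zero) down to
#'   \code{lambda_min_ratio} times it.
#' @param nlambda,lambda_min_ratio Grid controls (default 100, 0.001).
#' @param family \code{"binomial"} (default) or \code{"gaussian"}.
#' @param group_multiplier Per-group penalty multipliers \eqn{m_j}
#'   (named or in group order); default 1 for every group.
#' @param tol Convergence tolerance on the coefficient sup-norm change.
#' @param max_iter Sweep cap per lambda; non-convergence is a warning.
#' @return Object of class \code{glasso_path}.
#' @export
fit_path <- function(design, lambda = NULL, nlambda = 100L,
                     lambda_min_ratio = 0.001, family = c("binomial", "gaussian"),
                     group_multiplier = NULL, tol = 1e-7, max_iter = 10000L) {
  family <- match.arg(family)
  y <- design$y
  n <- length(y)
  if (n == 0L) stop("empty design")
  if (family == "binomial" && (all(y == 0) || all(y == 1))) {
    stop("outcome has a single class")
  }
  on <- orthonormalize_design(design)
  Q <- on$Q; groups <- on$groups
  gidx <- lapply(groups, function(g) which(design$group == g))
  names(gidx) <- groups
  m <- stats::setNames(rep(1, length(groups)), groups)
  if (!is.null(group_multiplier)) {
    if (!is.null(names(group_multiplier))) m[names(group_multiplier)] <- group_multiplier
    else m[] <- group_multiplier
  }
  v <- if (family == "binomial") 0.25 else 1

  mean_y <- mean(y)
  b0_null <- if (family == "binomial") stats::qlogis(mean_y) else mean_y
  r0 <- y - mean_y
  if (is.null(lambda)) {
    lam_max <- max(vapply(groups, function(g)
      sqrt(sum((crossprod(Q[, gidx[[g]], drop = FALSE], r0) / n)^2)) / m[[g]], 0))
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
    nlambda <- length(lambda)
  }

  p_tot <- ncol(Q)
  Qg <- lapply(gidx, function(jj) Q[, jj, drop = FALSE])
  gamma <- rep(0, p_tot); b0 <- b0_null
  eta <- rep(b0, n)
  betas <- matrix(0, p_tot, nlambda, dimnames = list(colnames(design$X), NULL))
  intercepts <- dev <- numeric(nlambda)
  dfs <- integer(nlambda); converged <- logical(nlambda)

  for (k in seq_len(nlambda)) {
    lam <- lambda[k]
    # one majorized blockwise sweep over `gs`; returns the sup-norm change
    sweep_groups <- function(gs) {
      delta_max <- 0
      r <- y - (if (family == "binomial") stats::plogis(eta) else eta)
      step <- mean(r) / v
      if (abs(step) > 0) {
        b0 <<- b0 + step; eta <<- eta + step; delta_max <- abs(step)
        r <- r - step * v  # first-order residual update; exact values refreshed per group
      }
      for (g in gs) {
        jj <- gidx[[g]]
        r <- y - (if (family == "binomial") stats::plogis(eta) else eta)
        u <- gamma[jj] + as.vector(crossprod(Qg[[g]], r)) / (v * n)
        nu <- sqrt(sum(u^2))
        g_new <- max(0, 1 - lam * m[[g]] / (v * nu)) * u
        d <- g_new - gamma[jj]
        if (any(d != 0)) {
          eta <<- eta + as.vector(Qg[[g]] %*% d)
          gamma[jj] <<- g_new
          delta_max <- max(delta_max, max(abs(d)))
        }
      }
      delta_max
    }
    # active-set cycling: converge on the active groups, then one full
    # sweep to let groups enter/leave; stop when the full sweep is quiet
    ok <- FALSE
    sweeps <- 0L
    while (sweeps < max_iter) {
      delta_full <- sweep_groups(groups); sweeps <- sweeps + 1L
      active <- groups[vapply(groups, function(g) any(gamma[gidx[[g]]] != 0), TRUE)]
      inner_ok <- length(active) == 0L
      while (sweeps < max_iter && !inner_ok) {
        d_in <- sweep_groups(active); sweeps <- sweeps + 1L
        if (d_in < tol) inner_ok <- TRUE
      }
      if (delta_full < tol && inner_ok) { ok <- TRUE; break }
    }
    if (!ok) warning(sprintf("fit_path: lambda[%d] = %.4g did not converge in %d sweeps",
                             k, lam, max_iter))
    converged[k] <- ok
    # back-transform to the original dummy scale
    beta <- numeric(p_tot)
    for (g in groups) {
      jj <- gidx[[g]]
      beta[jj] <- on$back[[g]] %*% gamma[jj]
    }
    betas[, k] <- beta
    intercepts[k] <- b0 - sum(on$centers * beta)
    if (family == "binomial") {
      p_hat <- stats::plogis(eta)
      p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
      dev[k] <- -2 * sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
    } else {
      dev[k] <- sum((y - eta)^2)
    }
    dfs[k] <- sum(abs(beta) > 1e-10) + 1L
  }
  aic <- dev + 2 * dfs
  bic <- dev + log(n) * dfs
  gcv <- dev / (n * (1 - dfs / n)^2)
  structure(list(lambda = lambda, beta = betas, intercept = intercepts,
                 deviance = dev, df = dfs, aic = aic, bic = bic, gcv = gcv,
                 group = design$group, groups = groups, family = family,
                 n = n, converged = converged),
            class = "glasso_path")
}

#' Groups with nonzero coefficients at one path point
#' @noRd
active_groups <- function(path, k) {
  b <- path$beta[, k]
  unique(path$group[abs(b) > 1e-10])
}

#' Linear predictor of a fitted path on new data
#' @noRd
predict_glasso <- function(path, X, k) {
  as.vector(path$intercept[k] + X %*% path$beta[, k])
}

#' Select lambda on a fitted path by an information criterion
#'
#' Degrees of freedom are counted as the number of nonzero coefficients
#' plus the intercept. Ties are resolved toward the smallest lambda
#' (densest model) and noted.
#'
#' @param path A \code{glasso_path}.
#' @param criterion \code{"BIC"} (default), \code{"AIC"} or \code{"GCV"}.
#' @return List: \code{lambda}, \code{index}, \code{criterion},
#'   \code{value}, \code{groups} (selected), \code{coefficients},
#'   \code{intercept}.
#' @export
select_ic <- function(path, criterion = c("BIC", "AIC", "GCV")) {
  criterion <- match.arg(criterion)
  val <- switch(criterion, BIC = path$bic, AIC = path$aic, GCV = path$gcv)
  best <- min(val)
  ties <- which(val <= best + 1e-12)
  if (length(ties) > 1L) message("select_ic: criterion tie; choosing the smallest lambda")
  k <- max(ties)  # lambdas are decreasing, so max index = smallest lambda
  list(lambda = path$lambda[k], index = k, criterion = criterion, value = val[k],
       groups = active_groups(path, k),
       coefficients = path$beta[, k], intercept = path$intercept[k])
}

#' Cross-validated lambda for the group LASSO
#'
#' Stratified k-fold cross-validation over a lambda grid shared across
#' folds; the CV error is the mean held-out binomial deviance per
#' observation, and \code{lambda_min} minimizes it.
#'
#' @param design A \code{grouped_design}.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param ... Passed to \code{\link{fit_path}}.
#' @return Object of class \code{cv_glasso}: \code{lambda},
#'   \code{cv_error}, \code{lambda_min}, \code{index_min},
#'   \code{selected_groups} (full-data fit at lambda_min),
#'   \code{fold_assignments}, \code{path} (full-data path).
#' @export
cv_lambda <- function(design, k = 10L, seed = 1L, ...) {
  y <- design$y; n <- length(y)
  stopifnot(k >= 2L, n >= k)
  full <- fit_path(design, ...)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  if (min(table(y)) < k) {
    message("cv_lambda: a class has fewer members than folds; some folds miss a class")
  }
  nl <- length(full$lambda)
  dev_sum <- numeric(nl); n_held <- 0L
  for (fold in seq_len(k)) {
    test <- folds == fold
    d_tr <- design
    d_tr$X <- design$X[!test, , drop = FALSE]
    d_tr$y <- design$y[!test]
    p_tr <- fit_path(d_tr, lambda = full$lambda, ...)
    for (j in seq_len(nl)) {
      eta <- predict_glasso(p_tr, design$X[test, , drop = FALSE], j)
      p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
      dev_sum[j] <- dev_sum[j] - 2 * sum(y[test] * log(p) + (1 - y[test]) * log(1 - p))
    }
    n_held <- n_held + sum(test)
  }
  cv_error <- dev_sum / n_held
  idx <- max(which(cv_error <= min(cv_error) + 1e-12))
  structure(list(lambda = full$lambda, cv_error = cv_error,
                 lambda_min = full$lambda[idx], index_min = idx,
                 selected_groups = active_groups(full, idx),
                 fold_assignments = folds, path = full),
            class = "cv_glasso")
}
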