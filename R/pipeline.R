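# End-to-end orchestration: simulate -> eligibility/coding -> univariate
# stats -> group-LASSO selection -> network learning -> inference ->
# evaluation, with one master seed fanned out to per-stage seeds and
# every artifact stamped with the configuration hash.

#' Pipeline configuration
#'
#' Validated configuration for \code{\link{run_pipeline}}; unknown
#' fields are rejected. Defaults reproduce the package's reference
#' study conditions.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_patients Synthetic cohort size.
#' @param lab_missing_rate Missing-at-random lab masking rate.
#' @param exclusion_rates Injected ineligibility rates (see
#'   \code{\link{cohort_params}}).
#' @param glasso_criterion Information criterion for lambda selection.
#' @param glasso_nlambda Path length.
#' @param glasso_cv_k Folds for the cross-validated lambda (0 disables).
#' @param bn_tabu_len,bn_max_parents,bn_smoothing Structure/parameter
#'   learning controls.
#' @param bn_blacklist Optional arcs never added (2-column matrix).
#' @param eval_cv_k Folds for pipeline cross-validation (0 disables).
#' @param ci_method AUC interval method.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 2395L, lab_missing_rate = 0,
                            exclusion_rates = c(short_stay = 0, baseline_rrt = 0, single_scr = 0),
                            glasso_criterion = "BIC", glasso_nlambda = 100L,
                            glasso_cv_k = 10L, bn_tabu_len = 10L,
                            bn_max_parents = 8L, bn_smoothing = 1,
                            bn_blacklist = NULL, eval_cv_k = 10L,
                            ci_method = "delong") {
  stopifnot(glasso_criterion %in% c("BIC", "AIC", "GCV"),
            ci_method %in% c("delong", "bootstrap"),
            n_patients > 0, glasso_nlambda >= 2)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 lab_missing_rate = lab_missing_rate,
                 exclusion_rates = exclusion_rates,
                 glasso_criterion = glasso_criterion,
                 glasso_nlambda = as.integer(glasso_nlambda),
                 glasso_cv_k = as.integer(glasso_cv_k),
                 bn_tabu_len = as.integer(bn_tabu_len),
                 bn_max_parents = as.integer(bn_max_parents),
                 bn_smoothing = bn_smoothing, bn_blacklist = bn_blacklist,
                 eval_cv_k = as.integer(eval_cv_k), ci_method = ci_method),
            class = "pipeline_config")
}

#' Abnormal-labs and corrected-labs evidence scenarios for a network
#'
#' Builds the paired evidence sets used for the counterfactual-style
#' readout: the "abnormal" scenario sets every AKI-relevant node
#' present in the network to its adverse level (anemia, hyponatremia,
#' low eGFR, hyperuricemia, leukemia), the "corrected" scenario to the
#' normal level.
#'
#' @param net A \code{bn}.
#' @return Named list of two evidence lists.
#' @export
default_scenarios <- function(net) {
  abnormal <- list(hemoglobin_low = "yes", sodium_band = "hypo",
                   egfr_band = "<=59", sua_band = ">=481", hm_category = "leukemia")
  corrected <- list(hemoglobin_low = "no", sodium_band = "normal",
                    egfr_band = ">=90", sua_band = "<=359", hm_category = "leukemia")
  nodes <- setdiff(net$dag$nodes, "aki")
  list(abnormal = abnormal[names(abnormal) %in% nodes],
       corrected = corrected[names(corrected) %in% nodes])
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> code -> univariate stats -> group-LASSO ->
#' network learning -> scenario inference -> evaluation on a synthetic
#' cohort. Reruns with the same configuration are byte-identical.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param outdir Optional directory; when given, every artifact is
#'   written there (CSV/JSON, all stamped with the config hash).
#' @return Object of class \code{aki_pipeline}: cohort, coded table,
#'   univariate report, path/selection, network, AKI CPD table,
#'   scenarios, evaluation, provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  provenance <- list(
    config = unclass(config)[setdiff(names(unclass(config)), "bn_blacklist")],
    config_hash = config_hash(jsonlite::toJSON(
      unclass(config)[setdiff(names(unclass(config)), "bn_blacklist")],
      auto_unbox = TRUE, digits = NA)),
    seed = seed)

  # 1. simulate
  params <- cohort_params(n_patients = config$n_patients, seed = seed,
                          lab_missing_rate = config$lab_missing_rate,
                          exclusion_rates = config$exclusion_rates)
  cohort <- simulate_cohort(params, seed = stage_seed(seed, 1L))

  # 2. eligibility + coding
  elig <- apply_eligibility(cohort)
  coded <- code_cohort(elig$eligible)

  # 3. univariate statistics
  report <- table1_report(coded)

  # 4. group-LASSO selection
  design <- build_design(coded)
  path <- fit_path(design, nlambda = config$glasso_nlambda)
  selection <- select_ic(path, config$glasso_criterion)
  cv <- if (config$glasso_cv_k >= 2L) {
    cv_lambda(design, k = config$glasso_cv_k, seed = stage_seed(seed, 2L),
              nlambda = config$glasso_nlambda)
  }

  # 5. network learning on the selected variables + outcome
  nodes <- union(selection$groups, "aki")
  dag <- tabu_learn(coded, nodes = nodes, tabu_len = config$bn_tabu_len,
                    max_parents = config$bn_max_parents,
                    blacklist = config$bn_blacklist,
                    seed = stage_seed(seed, 3L))
  net <- suppressWarnings(fit_cpts(dag, coded, smoothing = config$bn_smoothing,
                                   levels = aki_levels[nodes]))
  aki_cpd <- cpd_table(net, "aki")
  # reference CPD of AKI given eGFR band, anemia and sodium band (the
  # clinical summary layout), independent of the learned parent set
  ref_nodes <- c("egfr_band", "hemoglobin_low", "sodium_band", "aki")
  ref_dag <- bn_dag(ref_nodes, cbind(ref_nodes[1:3], "aki"))
  cpd_reference <- cpd_table(suppressWarnings(
    fit_cpts(ref_dag, coded, smoothing = config$bn_smoothing,
             levels = aki_levels[ref_nodes])), "aki")

  # 6. scenario inference
  scen <- scenario_inference(net, default_scenarios(net),
                             seed = stage_seed(seed, 4L),
                             engine = "exact")

  # 7. evaluation
  scores <- predict_bn(net, coded, seed = stage_seed(seed, 5L))
  labels <- as.integer(coded$aki == "yes")
  roc <- auc(scores, labels, ci_method = config$ci_method,
             seed = stage_seed(seed, 6L))
  baseline <- logistic_baseline(coded, selection$groups)
  cv_eval <- if (config$eval_cv_k >= 2L) {
    crossvalidate(coded, k = config$eval_cv_k, seed = stage_seed(seed, 7L),
                  smoothing = config$bn_smoothing, full_scores = scores)
  }

  out <- structure(list(
    provenance = provenance, params = params, cohort = cohort,
    exclusion_log = elig$exclusion_log, coded = coded, report = report,
    design = design, path = path, selection = selection, cv_lambda = cv,
    dag = dag, net = net, aki_cpd = aki_cpd, cpd_reference = cpd_reference,
    scenarios = scen,
    scores = scores, roc = roc, baseline = baseline, cv_eval = cv_eval),
    class = "aki_pipeline")
  if (!is.null(outdir)) write_pipeline_artifacts(out, outdir)
  out
}

#' Write every pipeline artifact to a directory
#'
#' Text formats only (CSV/JSON/BIF); all JSON artifacts embed the
#' provenance block so a rerun with the same configuration is
#' byte-identical.
#' @param result An \code{aki_pipeline}.
#' @param outdir Directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  wjson <- function(x, file) {
    jsonlite::write_json(c(list(provenance = result$provenance), x), p(file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  write_cohort_csv(result$cohort, p("cohort_patients.csv"), p("cohort_scr_series.csv"))
  write_coded_csv(result$coded, p("coded_cohort.csv"))
  utils::write.csv(result$report$rows, p("univariate_report.csv"), row.names = FALSE)
  wjson(list(overall = result$report$overall, notes = result$report$notes),
        "univariate_overall.json")
  utils::write.csv(data.frame(lambda = result$path$lambda, df = result$path$df,
                              deviance = result$path$deviance, aic = result$path$aic,
                              bic = result$path$bic, gcv = result$path$gcv),
                   p("glasso_path.csv"), row.names = FALSE)
  wjson(list(criterion = result$selection$criterion, lambda = result$selection$lambda,
             groups = result$selection$groups,
             lambda_min_cv = if (!is.null(result$cv_lambda)) result$cv_lambda$lambda_min,
             cv_selected = if (!is.null(result$cv_lambda)) result$cv_lambda$selected_groups),
        "glasso_selection.json")
  bn_to_json(result$net, p("network.json"))
  write_bif(result$net, p("network.bif"))
  utils::write.csv(result$aki_cpd, p("aki_cpd_table.csv"), row.names = FALSE)
  utils::write.csv(result$cpd_reference, p("aki_cpd_reference.csv"), row.names = FALSE)
  utils::write.csv(result$scenarios, p("scenario_inference.csv"), row.names = FALSE)
  utils::write.csv(data.frame(threshold = result$roc$thresholds,
                              sensitivity = result$roc$sensitivity,
                              specificity = result$roc$specificity),
                   p("roc_points.csv"), row.names = FALSE)
  wjson(list(auc_bn = result$roc$auc, ci = c(result$roc$ci_low, result$roc$ci_high),
             auc_logistic = if (!is.null(result$baseline$roc)) result$baseline$roc$auc,
             auc_cv = if (!is.null(result$cv_eval)) result$cv_eval$pooled$auc,
             cv_ci = if (!is.null(result$cv_eval))
               c(result$cv_eval$pooled$ci_low, result$cv_eval$pooled$ci_high),
             accuracy_p = if (!is.null(result$cv_eval)) result$cv_eval$accuracy_p_value),
        "evaluation.json")
  invisible(outdir)
}

#' @export
print.aki_pipeline <- function(x, ...) {
  cat(sprintf("AKI pipeline run (seed %d, n = %d)\n", x$provenance$seed,
              x$params$n_patients))
  cat(sprintf("  eligible %d, AKI %.1f%%\n", nrow(x$coded), x$report$overall$pct))
  cat(sprintf("  gLASSO (%s) selected: %s\n", x$selection$criterion,
              paste(x$selection$groups, collapse = ", ")))
  cat(sprintf("  network arcs: %d; AKI parents: %s\n", nrow(dag_arcs(x$dag)),
              paste(x$dag$parents[["aki"]], collapse = ", ")))
  cat(sprintf("  AUC (BN) %.3f", x$roc$auc))
  if (!is.null(x$baseline$roc)) cat(sprintf(", logistic %.3f", x$baseline$roc$auc))
  if (!is.null(x$cv_eval)) cat(sprintf(", %d-fold CV %.3f", length(x$cv_eval$fold_auc),
                                       x$cv_eval$pooled$auc))
  cat("\n")
  invisible(x)
}
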