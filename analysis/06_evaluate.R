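#!/usr/bin/env Rscript
# Stage 6: predictive evaluation.
#
# Scores every patient by the network posterior P(AKI | observed
# predictors), compares against the unpenalized logistic score model on
# the selected predictors, and re-runs the whole selection -> structure
# -> parameters pipeline in stratified 10-fold cross-validation.

library(akinet)

coded <- read_coded_csv("results/coded_cohort.csv")
net <- bn_from_json("results/network.json")
sel <- jsonlite::fromJSON("results/glasso_selection.json")

scores <- predict_bn(net, coded, seed = 5)
labels <- as.integer(coded$aki == "yes")
roc_bn <- auc(scores, labels)
cat("BN model: "); print(roc_bn)

base <- logistic_baseline(coded, sel$bic$groups)
cat("logistic score model: "); print(base$roc)

cv <- crossvalidate(coded, k = 10, seed = 6, full_scores = scores)
cat("10-fold CV: "); print(cv$pooled)
cat(sprintf("accuracy comparison p-value (full vs CV, Youden threshold): %.3f\n",
            cv$accuracy_p_value))

write.csv(data.frame(threshold = roc_bn$thresholds, sensitivity = roc_bn$sensitivity,
                     specificity = roc_bn$specificity),
          "results/roc_points.csv", row.names = FALSE)
jsonlite::write_json(
  list(auc_bn = roc_bn$auc, ci_bn = c(roc_bn$ci_low, roc_bn$ci_high),
       auc_logistic = base$roc$auc,
       auc_cv = cv$pooled$auc, ci_cv = c(cv$pooled$ci_low, cv$pooled$ci_high),
       fold_auc = cv$fold_auc, accuracy_p = cv$accuracy_p_value),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/roc_points.csv, results/evaluation.json\n")
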