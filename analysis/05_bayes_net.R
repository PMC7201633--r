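#!/usr/bin/env Rscript
# Stage 5: Bayesian network learning and inference.
#
# Learns the network structure over the BIC-selected variables plus the
# AKI outcome by BIC-scored tabu search, fits maximum-likelihood CPTs
# (pseudo-count 1), tabulates the AKI conditional distribution, and runs
# the abnormal-vs-corrected evidence scenarios.

library(akinet)

coded <- read_coded_csv("results/coded_cohort.csv")
sel <- jsonlite::fromJSON("results/glasso_selection.json")
nodes <- union(sel$bic$groups, "aki")

dag <- tabu_learn(coded, nodes = nodes, seed = 3)
cat("learned arcs:\n")
print(dag_arcs(dag))
cat("AKI parents:", paste(dag$parents[["aki"]], collapse = ", "), "\n")

net <- suppressWarnings(fit_cpts(dag, coded, smoothing = 1,
                                 levels = aki_levels[nodes]))
bn_to_json(net, "results/network.json")
write_bif(net, "results/network.bif")

write.csv(cpd_table(net, "aki"), "results/aki_cpd_learned.csv", row.names = FALSE)
ref_nodes <- c("egfr_band", "hemoglobin_low", "sodium_band", "aki")
ref_net <- suppressWarnings(fit_cpts(
  bn_dag(ref_nodes, cbind(ref_nodes[1:3], "aki")), coded, smoothing = 1,
  levels = aki_levels[ref_nodes]))
ref_cpd <- cpd_table(ref_net, "aki")
write.csv(ref_cpd, "results/aki_cpd_reference.csv", row.names = FALSE)
cat(sprintf("reference CPD (eGFR x anemia x sodium): worst row %.1f%%, best row %.1f%%\n",
            max(ref_cpd$pct_yes), min(ref_cpd$pct_yes)))

scen <- scenario_inference(net, default_scenarios(net), seed = 4, engine = "exact")
print(scen)
write.csv(scen, "results/scenario_inference.csv", row.names = FALSE)
cat("wrote results/{network.json, network.bif, aki_cpd_*.csv, scenario_inference.csv}\n")
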