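#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic cohort.
#
# Draws 2395 hematologic-malignancy admissions from the generator's
# ground-truth network (marginals calibrated to the published cohort;
# dependency skeleton HM -> {hemoglobin, eGFR} <- diabetes and
# {age, anemia, eGFR, sodium, potassium} -> AKI) and writes the patient
# table plus the long-format serum-creatinine series.

library(akinet)

seed <- 1L
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

params <- cohort_params(n_patients = 2395L)
cohort <- simulate_cohort(params, seed = seed)
print(cohort)

truth <- attr(cohort, "truth")
cat(sprintf("AKI-destined: %d (%.1f%%); stages 1/2/3: %s\n",
            sum(truth$aki == "yes"), 100 * mean(truth$aki == "yes"),
            paste(table(truth$aki_stage[truth$aki_stage > 0]), collapse = "/")))

write_cohort_csv(cohort, "results/cohort/patients.csv", "results/cohort/scr_series.csv")
bn_to_json(params$truth, "results/cohort/truth_network.json")
cat("wrote results/cohort/{patients.csv, scr_series.csv, truth_network.json}\n")
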