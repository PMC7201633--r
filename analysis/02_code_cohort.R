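#!/usr/bin/env Rscript
# Stage 2: eligibility screening, KDIGO AKI detection, discretization.
#
# Reads the cohort written by stage 1, applies the eligibility filters
# (admissions >= 24 h, no baseline dialysis/RRT, repeated SCr tests),
# detects and stages AKI from each creatinine series, and codes the
# admission labs into the categorical analysis bands.

library(akinet)

cohort <- read_cohort_csv("results/cohort/patients.csv", "results/cohort/scr_series.csv")
elig <- apply_eligibility(cohort)
cat("exclusions:", paste(names(elig$exclusion_log), elig$exclusion_log,
                         sep = "=", collapse = ", "), "\n")

coded <- code_cohort(elig$eligible)
cat(sprintf("eligible %d; AKI %d (%.1f%%); stages: %s\n",
            nrow(coded), sum(coded$aki == "yes"), 100 * mean(coded$aki == "yes"),
            paste(table(coded$aki_stage[coded$aki_stage > 0]), collapse = "/")))

write_coded_csv(coded, "results/coded_cohort.csv")
cat("wrote results/coded_cohort.csv (+ .dict.json data dictionary)\n")
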