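# akinet

Acute kidney injury (AKI) risk modelling for hospitalized patients with
hematologic malignancies (HM): an end-to-end, tested R implementation of
the *group-LASSO screened discrete Bayesian network* analysis pipeline,
exercised on a synthetic cohort generator with a known ground-truth
dependency graph and validated exactly against the published univariate
statistics of a 2395-patient HM cohort (370 AKI episodes, 15.4 %).

The pipeline is aimed at clinical epidemiologists and methodologists who
want a reproducible, scriptable version of this modelling strategy:

1. **KDIGO coding** — AKI detection and staging from serum-creatinine
   series (≥ 26.5 µmol/L rise within 48 h, or ≥ 1.5× the rolling 168-h
   baseline; stages at < 2.0×, 2.0–< 3.0×, ≥ 3.0× or ≥ 353.6 µmol/L),
   eligibility filtering, and discretization into the standard clinical
   bands.
2. **Univariate epidemiology** — Pearson χ², Cochran–Mantel–Haenszel
   trend for ordered bands, and crude odds ratios
   OR = ad/bc with Woolf intervals exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)).
3. **Group LASSO** — penalized logistic regression minimizing
   (1/n)·ℓ(β) + λ·Σⱼ‖βⱼ‖₂ over whole dummy groups, fitted by block
   coordinate descent with group soft-thresholding on orthonormalized
   groups; λ by AIC/BIC/GCV or cross-validated `lambda.min`.
4. **Bayesian network** — BIC-scored tabu-search structure learning
   (score Σᵢ[LLᵢ − (dᵢ/2)·ln N]), maximum-likelihood CPTs, exact
   enumeration, likelihood weighting and logic sampling for
   P(AKI | any subset of findings), plus scenario ("abnormal vs
   corrected labs") inference.
5. **Evaluation** — Mann–Whitney AUC with DeLong intervals, a logistic
   score-model baseline, and stratified 10-fold cross-validation of the
   whole selection → structure → parameters pipeline.

Because the original patient-level data are not public, the package
ships a cohort generator whose marginals are calibrated to the published
table and whose dependency skeleton
(HM → {hemoglobin, eGFR} ← diabetes; {age, anemia, eGFR, Na, K} → AKI)
provides ground truth for recovery experiments. See
`vignettes/aki-bn-methods.Rmd` for the full methods account.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
reference synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_code_cohort.R
Rscript analysis/03_univariate_stats.R
Rscript analysis/04_group_lasso.R
Rscript analysis/05_bayes_net.R
Rscript analysis/06_evaluate.R
```

Stage 3 reproduces the published univariate table exactly from the
packaged counts:

```
published counts: 2395 patients, AKI 15.4%
  gender=female: OR 1.44 (1.16-1.80)
  diabetes=yes: OR 1.58 (1.26-1.98)
  treatment=ASCT: OR 4.37 (2.04-9.36)
  hemoglobin_low=yes: OR 3.85 (2.93-5.04)
  sodium_band=hypo: OR 5.84 (4.50-7.59)
  potassium_band=hyper: OR 39.69 (13.45-117.15)
  egfr_band=<=59: OR 13.75 (9.52-19.86)
```

(the Pearson χ² values match too: 10.561 for gender, 15.748 for
diabetes). Stages 4–6 then run the model pipeline on the synthetic
cohort (seed 1):

```
BIC selection: lambda = 0.01094 (log lambda = -4.515), 5 groups:
  age_band, egfr_band, hemoglobin_low, potassium_band, sodium_band
10-fold CV: lambda.min = 0.00584, 11 groups
AKI parents: egfr_band        # remaining direct causes attach as skeleton edges
reference CPD (eGFR x anemia x sodium): worst row 78.6%, best row 3.2%
   scenario  posterior  marginal      delta
1  abnormal 0.77948056 0.1477207  0.6317598
2 corrected 0.04190308 0.1477207 -0.1058177
BN model: AUC 0.828 (95% CI 0.805-0.852, delong)
logistic score model: AUC 0.828 (95% CI 0.804-0.852, delong)
10-fold CV: AUC 0.821 (95% CI 0.797-0.846, delong)
```

Reading this: the group LASSO keeps exactly the generator's five direct
AKI causes at the BIC optimum; the learned skeleton connects all of them
to AKI (weak causes may attach as children — orientation within a
score-equivalence class is not identified); the conditional probability
of AKI ranges from ~3 % (normal eGFR/hemoglobin/sodium) to ~79 % (low
eGFR, anemia, hyponatremia); and conditioning on corrected labs drops
the inferred AKI probability from 78 % to 4 %. These synthetic-cohort
numbers are workflow analogues, not reproductions of the original
cohort's fitted model.

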