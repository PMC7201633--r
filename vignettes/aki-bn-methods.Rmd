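---
title: "Methods: group-LASSO screened Bayesian networks for AKI risk in hematologic malignancy inpatients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-LASSO screened Bayesian networks for AKI risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(akinet)
```

## The problem and the modelling strategy

Hospitalized patients with hematologic malignancies (lymphoma, leukemia,
multiple myeloma) develop acute kidney injury (AKI) at high rates, and the
risk factors — malignancy category, anti-tumor treatment, anemia, renal
function, electrolyte disturbances — are strongly interdependent, which
makes a plain multivariable logistic model awkward both statistically
(collinearity) and clinically (it cannot score a patient with partially
missing labs). The pipeline implemented here combines three stages:

1. **Univariate epidemiology.** Every admission variable is discretized
   into clinical bands and cross-tabulated against the KDIGO-coded AKI
   outcome; Pearson chi-square (nominal variables), the
   Cochran–Mantel–Haenszel linear trend (ordered bands), and crude odds
   ratios with Woolf intervals summarize the crude associations.
2. **Group-LASSO screening.** Each categorical variable's dummy columns
   form one penalty group, so variables enter or leave the logistic model
   whole. The screening removes noise variables before network learning,
   which keeps the graph small and suppresses false arcs.
3. **Discrete Bayesian network.** A DAG over the selected variables plus
   AKI is learned by BIC-scored tabu search; per-node conditional
   probability tables (CPTs) are fitted by maximum likelihood. The fitted
   network supports exact enumeration on small state spaces and
   likelihood-weighting / logic-sampling inference generally, so the
   probability of AKI can be computed from *any* subset of observed
   findings.

## KDIGO coding

AKI is detected from the serum-creatinine (SCr) series alone (urine
output is not used): an absolute rise of at least 26.5 µmol/L
(0.3 mg/dL) between two measurements at most 48 h apart, or a
measurement reaching at least 1.5× the rolling baseline, defined as the
minimum SCr over the preceding 168 h. Staging takes the maximum over the
admission: stage 1 up to a 2.0-fold rise, stage 2 for 2.0–<3.0-fold,
stage 3 for ≥3.0-fold or an SCr of 353.6 µmol/L (4.0 mg/dL) during AKI.
Two conventions had to be fixed where the clinical definition is
operationally under-specified: the 48-hour clause is evaluated over *all*
measurement pairs (not only against the admission value), and the
"baseline" of the fold clause is the rolling 168-hour minimum, the usual
EMR convention. With these choices the coder is equivalent to an
exhaustive scan over measurement pairs, and the test suite checks it
against an independently written O(m²) oracle on 1000 random series.
The stage-2 band is the standard KDIGO 2.0–<3.0-fold interval.

Discretization cutoffs are the published clinical bands: ALT ≥ 40 U/L,
AST ≥ 35 U/L, TBiL ≥ 20.4 µmol/L, SCr ≥ 115 µmol/L, eGFR bands at
90/60 mL/min/1.73 m², SUA bands at 360/421/481 µmol/L, albumin < 35 g/L,
hemoglobin < 115 g/L (anemia), WBC ≥ 9.5×10⁹/L, sodium reference
137–147 mmol/L, potassium reference 3.5–5.3 mmol/L, age bands ≤29 /
30–49 / 50–69 / ≥70 years (ages are floored before banding, so 29.6
years is "≤29"). Missing labs stay missing; nothing is imputed.

## The synthetic cohort generator

No patient-level data accompany the published study, so the package
ships a generator whose defaults *are* the study conditions: 2395
admissions, root-variable marginals equal to the published
per-variable frequencies (e.g. 1375/2395 male, 814/2395 diabetic), an
overall AKI probability calibrated to 370/2395 = 15.4 %, and an AKI
stage mix of 308/41/21. The generator is itself a discrete Bayesian
network over the coded variables with a known skeleton:

* HM category → anemia (anemia probability 0.50 / 0.80 / 0.78 for
  lymphoma / leukemia / myeloma);
* HM category and diabetes → eGFR band (band probabilities shift toward
  renal insufficiency for leukemia/myeloma and diabetics);
* age band, anemia, eGFR band, sodium band, potassium band → AKI,
  through a monotone logistic response (log-odds +1.3 for age ≤29,
  +0.7 for ≥70, +1.5 for anemia, +0.9/+2.8 for eGFR 60–89/≤59, +1.9/+1.7
  for hypo-/hypernatremia, +1.7/+3.3 for hypo-/hyperkalemia), with the
  intercept solved numerically so the implied marginal equals the target
  incidence.

The effect sizes are deliberately strong — they were chosen once, as
plausible-but-clear signals consistent with the direction and ordering
of the published crude odds ratios, to make structure- and
group-recovery experiments meaningful; they are not estimates of the
original cohort's parameters. All remaining variables (hypertension,
admission type, treatment, liver panel, SUA, albumin, WBC) are
independent roots: the published study reports no pairwise associations
among predictors, so any further dependence would be invented.

Continuous labs are drawn uniformly within the sampled band; SCr
baselines are uniform on 40–120 µmol/L. AKI-destined patients receive a
creatinine series that multiplies baseline by a stage-specific fold
factor (1.55–1.95 / 2.05–2.85 / 3.05–3.90) inside a 48-hour window;
non-AKI series jitter within ±9 % of baseline, which can trigger
neither KDIGO clause. This is the minimal mechanism that exercises both
clauses of the coder; it does not emulate real creatinine kinetics
(recovery slopes, measurement frequency driven by acuity), nor are the
admission SCr value and the eGFR band linked through a GFR equation.
Consequently, passing tests demonstrate the correctness and calibration
of the *pipeline*, not clinical validity on real EMR data.

Optional knobs inject ineligible admissions (short stays, baseline
dialysis/RRT, single SCr tests) and missing-at-random lab masking, to
exercise the eligibility filter and the missing-data contract.

## Group LASSO

The estimator minimizes, over the within-group-orthonormalized dummy
design (Q_j'Q_j = nI),

$$\frac{1}{n}\,\ell(\beta_0, \gamma) \;+\; \lambda \sum_j m_j \lVert \gamma_j \rVert_2 ,$$

with ℓ the binomial negative log-likelihood. The published estimator
display uses a squared-error loss, but the outcome is binary and the
reference tooling for this analysis fits the logistic family, so the
binomial deviance is used (a gaussian family is also implemented and
supplies a closed-form test anchor). The group multipliers default to
m_j = 1, matching the displayed penalty; grpreg-style √p_j scaling is
available via `group_multiplier`.

The path is fitted by block coordinate descent: the logistic loss is
majorized by its curvature bound v = 1/4, giving the group update
(1 − λ m_j /(v‖u_j‖))₊ u_j with u_j the partial-residual projection.
Active-set cycling (converge on the active groups, then a full pass that
lets groups enter or leave) keeps sparse path points cheap. Defaults:
100 log-spaced λ from λ_max (the smallest λ with all groups zero, which
has a closed form) down to 0.001·λ_max, convergence at a coefficient
sup-norm change below 1e-7, 10⁴ sweeps maximum, warm starts along the
path. At λ = 0 the fit agrees with the unpenalized `glm` MLE; at λ_max
the model is the null model with the prevalence-logit intercept — the
two analytic anchors of the test suite.

λ is selected either by an information criterion on the path (AIC, BIC,
GCV; df = nonzero coefficients + intercept; ties resolve to the densest
model) or by stratified k-fold cross-validation of the held-out
deviance (`lambda.min`). A practical note the tests make explicit:
under a permuted (signal-free) outcome the BIC selector collapses to
the empty model essentially always, while CV's `lambda.min` frequently
keeps one or more noise groups — minimum-CV selection is known to
overselect, which is why the pipeline's default selector is BIC.
Reference (dummy-omitted) levels follow the published table's
"OR 1.00" rows.

## Bayesian network learning and inference

The network score is the decomposable BIC,
$$\textstyle\sum_i \big[\,LL_i - \tfrac{d_i}{2}\log N\,\big],$$
with LL_i the multinomial log-likelihood of node i given its parents
and d_i = (L_i − 1)·∏ parent levels. The published analysis names only
the search algorithm (tabu), not its score; BIC is the standard default
for discrete tabu search and is also the λ criterion used upstream, so
one criterion governs both stages. Search moves are single-arc add /
delete / reverse, acyclicity-checked; the tabu list (default length 10)
blocks the inverse of recent moves unless the move beats the best score
seen (aspiration); equal-score moves break ties lexicographically, so
learning is deterministic — the seed only matters for optional random
restarts. Whitelists force arcs, blacklists forbid them; AKI is *not*
constrained to be a sink. Complete cases are used for learning; partial
evidence is handled natively at inference time instead (no EM).

Because the outcome node aggregates several strong causes, the search
often attaches a weak cause (age) as a *child* of AKI rather than a
parent — the skeleton edge is recovered at a fraction of the parameter
cost of enlarging AKI's CPT. Recovery is therefore evaluated on the
skeleton (structural Hamming distance over undirected edges), which is
also the scale on which score-equivalent orientations are
indistinguishable.

CPTs are maximum-likelihood row frequencies, optionally with a
pseudo-count (the pipeline default is 1, which keeps rare parent
configurations away from hard zeros); never-observed parent rows fall
back to uniform with a warning so that inference cannot meet an
all-zero row.

Inference engines: exact enumeration (guarded to ≤ 2²⁰ joint states) is
the oracle; likelihood weighting samples non-evidence nodes
topologically and weights by the evidence likelihood, reporting
ratio-estimator Monte-Carlo standard errors and an effective sample
size; logic sampling is forward sampling with rejection. The tests
verify the documented variance ordering (likelihood weighting below
rejection at equal sample count) and the O(n^{-1/2}) error decay.
Scenario inference batches evidence sets with a shared seed, so
"abnormal labs" vs "corrected labs" differ only in the evidence.

## Evaluation

Patients are scored by the posterior P(AKI = yes | observed predictors)
— exact when the state space allows, likelihood weighting otherwise,
cached per unique evidence configuration. AUC is the tie-corrected
Mann–Whitney concordance; the interval is DeLong's (a seeded bootstrap
is available), computed through pROC. The logistic score model on the
selected predictors is the comparison baseline, with a tiny ridge
refit on apparent separation. Cross-validation re-runs the *entire*
pipeline (selection → structure → parameters) inside each stratified
fold; pooled held-out scores give the CV AUC. The published comparison
of initial vs cross-validated accuracy by a "Mantel-Haenszel test" is
ambiguous; it is implemented — and labeled — as a chi-square on
correct/incorrect classification counts at each fit's Youden-optimal
threshold.

One caveat the package states rather than hides: the generator's AKI
mechanism *is* a logistic response of its parents, so the unpenalized
logistic baseline is essentially the Bayes-optimal scorer on synthetic
cohorts and the network model tracks it closely without necessarily
exceeding it. The published superiority of the network model over the
logistic score model is an empirical property of the original cohort,
not an invariant of the method.

## Problem sizes and numerical conventions

The reference analyses use the published cohort size (n = 2395) with
10-fold cross-validation for both λ and the pipeline; recovery
experiments use n = 5000 (20 replicate seeds) where selection/structure
consistency is the question, and n = 10⁴ for marginal-calibration
checks; sampling-inference validation uses 100 random ≤5-node networks
at 50 000 samples. The test suite scales some fixtures down (n =
500–2000, path lengths 20–40) to keep it quick; every size is stated in
the test or script that uses it. All randomness flows from explicit
seeds; a single master seed fans out to per-stage seeds, so each stage
is independently reproducible and a rerun of the pipeline is
byte-identical (the determinism check compares every written artifact).
Probability rows must sum to 1 within 1e-9; group-sparsity is asserted
at 1e-10; path deviance is non-increasing within 1e-6.

## Known limitations

* Synthetic cohorts are calibrated to the published *marginals* only;
  the joint distribution beyond the declared skeleton is a modelling
  choice, so numerical results on synthetic data (AUCs, CPD values,
  selected λ) are workflow analogues, not reproductions of the
  published model-level numbers.
* The CMH trend statistic with integer scores reproduces the published
  SUA value exactly but not the published age/eGFR values; the original
  scoring convention is unknown, so those are reported as diagnostics
  only.
* Arcs express probabilistic dependence, not causation; scenario
  "corrections" are conditioning exercises, not interventions.
* EM-based learning from incomplete records is out of scope; learning
  uses complete cases, and missingness is handled only at inference.
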