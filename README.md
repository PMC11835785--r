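# bnaf — Bayesian-network prediction of AF relapse after pulmonary vein isolation

Atrial fibrillation (AF) often recurs after catheter ablation. `bnaf` is an
R implementation of an explainable risk model for post-ablation relapse: a
discrete Bayesian network over twelve discretized clinical variables (sex,
age band, alcoholism, smoking, diabetes, high blood pressure, obstructive
sleep apnea, BMI class, preablation AF type, left-atrial volume band,
epicardial fat band, and the relapse outcome). It is aimed at
biostatisticians and clinical-modelling researchers who want the full
pipeline — structure learning, fitting, inference, validation — as tested,
scriptable functions.

The network factorizes the joint distribution as
P(x₁,…,x₁₂) = ∏ᵢ P(xᵢ | pa(xᵢ)). The package provides:

* **Constraint-aware structure learning** — hill climbing over the BIC
  score (log-likelihood − (log n)/2 per free parameter), starting from a
  clinical whitelist (the five ATLAS-score predictors plus epicardial fat
  and OSA forced into the outcome; relapse constrained to be a sink) with
  blacklists honored and determinism guaranteed by ordered move
  enumeration.
* **Bayesian CPT estimation** — Dirichlet posterior means under a uniform
  BDeu-style prior, p̂ = (N + α)/(N· + rα) with α = ESS/(rq), default
  equivalent sample size 1.
* **Exact inference under partial evidence** — full-joint enumeration
  (20,736 cells), with a variable-elimination engine as an independent
  cross-check; variables missing from a patient's record are simply
  marginalized, which is how the 5-, 6- and 7-predictor configurations
  work.
* **The resampling validation protocol** — bootstrap (out-of-bag testing)
  and hold-out 80:20 / 90:10 / 95:5; cycles repeat until every patient is
  tested ≥ 30 times; per-patient probabilities are averaged; AUC with a
  DeLong 95% CI and the Youden-optimal cutoff are computed on the averaged
  scores.
* **A calibrated synthetic registry** — the real 480-patient cohort is
  private, so `build_ground_truth()` constructs a generating network whose
  marginals match the published stratified count table exactly and whose
  outcome CPT is an additive-log-odds surrogate calibrated to the
  per-class relapse rates (e.g. P(relapse | OSA) = 35/50). All pipeline
  claims are demonstrated against it.

## Worked example

```r
library(bnaf)

gt     <- build_ground_truth()                  # calibrated generator
cohort <- sample_cohort(gt, 480, seed = 1)      # synthetic registry
st     <- ground_truth_structure()              # whitelist + learned arcs

fit <- fit_cpts(st, cohort, ess = 1)
query(fit, "relapse", evidence(sex = "female", age = "over65",
                               smoking = "false"))
#> P(relapse | sex = female, age = over65, smoking = false)
#>    false     true
#> 0.640286 0.359714

v <- run_validation(cohort, st, "full7", sampling_scheme("bootstrap"),
                    min_tests = 30, seed = 5)
v
#> Validation [bootstrap], 7 predictors, 121 cycles
#>   AUC 0.793 (95% CI 0.752-0.833), Youden cutoff 0.346
#>   per-patient tests: min 30, median 45
```

The query answers: for a non-smoking woman over 65, with every unmeasured
variable marginalized, the fitted network puts the relapse probability
near the cohort base rate (~0.34) — those three variables alone carry
little signal. The validation run reports the area under the ROC curve of
the averaged out-of-bag predictions using all seven parents of the
outcome as evidence; on synthetic cohorts the AUC ordering
full7 > easy6 (adds BMI to the five easy variables) > atlas5 (the five
easy variables alone) reproduces the qualitative finding that the two
imaging-derived predictors carry substantial weight, and that BMI can
partially stand in for its child, epicardial fat.

The `analysis/` directory holds the numbered workflow drivers —
`01_simulate_cohort.R` through `05_recovery_benchmarks.R` — which write
their tables under `results/` (cohort CSV, learned structure JSON + DOT,
profile probability table, per-scheme validation metrics, recovery
benchmarks).

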