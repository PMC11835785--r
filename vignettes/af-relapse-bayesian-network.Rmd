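---
title: "Predicting AF relapse after pulmonary vein isolation with a discrete Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting AF relapse after pulmonary vein isolation with a discrete Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Atrial fibrillation (AF) frequently recurs after catheter ablation by
pulmonary vein isolation (PVI). Clinicians want a patient-specific
probability of relapse computable from routinely available variables, that
still works when some measurements (typically the imaging-derived ones) are
missing, and whose reasoning is inspectable. `bnaf` implements such a tool
as a discrete Bayesian network over twelve discretized clinical variables —
sex, age band, alcoholism, smoking, diabetes, high blood pressure,
obstructive sleep apnea (OSA), BMI class, preablation AF type, indexed
left-atrial (LA) volume band, epicardial fat band, and the outcome, AF
relapse after the post-ablation blanking period.

A Bayesian network factorizes the joint distribution as
\[
P(x_1,\dots,x_{12}) \;=\; \prod_{i} P\!\left(x_i \mid \mathrm{pa}(x_i)\right),
\]
with one conditional probability table (CPT) per node. Everything the
package does — structure learning, fitting, risk queries, validation — is
built on this factorization.

```{r, eval = FALSE}
library(bnaf)
gt <- build_ground_truth()              # calibrated synthetic registry
cohort <- sample_cohort(gt, 480, seed = 1)
fit <- fit_cpts(ground_truth_structure(), cohort, ess = 1)
query(fit, "relapse", evidence(sex = "female", age = "over65",
                               smoking = "false"))
```

## Discretization conventions

All numeric measurements are binned before modelling. The interval
convention is: the first band is closed at its lower end, interior upper
ends are closed, and the top band is open-ended — so LA volume 100 mL/m²
falls in `le100`, and epicardial fat 4.61 cm³ in `over4.6`. Band edges are
age 45/65 years, LA volume 100/125 mL/m², epicardial fat 2.7/4.6 cm³. The
BMI classes are named (normal / overweight / obese) rather than numerically
defined in the source cohort description; the discretizer uses the WHO
edges 25 and 30 kg/m². Binary comorbidities are coded `"false"`/`"true"`,
and state labels are canonical lowercase tokens so that file round-trips
are bit-exact.

## Network structure: knowledge plus search

The structure is built in two steps, mirroring how such models are built
with domain experts:

1. **Whitelist.** Seven established relapse predictors — the five ATLAS
   score variables (age, sex, smoking, preablation AF type, LA volume)
   plus epicardial fat and OSA — are forced as parents of the outcome, and
   known risk-factor arcs feed the comorbidity nodes. The published graph
   names diabetes, high blood pressure and OSA as having "known risk
   factors" among the dataset's variables without enumerating the arcs;
   this package's editable default (`inst/extdata/default_constraints.json`)
   uses `bmi -> {diabetes, hbp, osa}` and `age -> {diabetes, hbp}`, and all
   structure-dependent code reads that file rather than hard-coding the
   choice. The outcome is blacklisted as a source: relapse is a sink.

2. **Search.** `hill_climb()` greedily applies the single arc move (add /
   delete / reverse) with the largest gain in the Bayesian Information
   Criterion,
   \[
   \mathrm{BIC} = \sum_i \left[\max_\theta \log
   L\!\left(x_i \mid \mathrm{pa}(x_i)\right)
   - \tfrac{\log n}{2}\, q_i (r_i - 1)\right],
   \]
   never touching whitelisted arcs, never adding blacklisted ones, and
   never creating a cycle, until no move improves the score.

Design choices where the procedure was genuinely open: moves are
enumerated in lexicographic (operation, parent, child) order and the first
maximal improvement is taken, making results deterministic without a seed;
there are no random restarts or tabu list (plain hill climbing is what the
approach calls for, and the score surface here is benign); the parent count
is unbounded by default (`max_parents` exists to protect CPT size on wider
schemas). BIC is score-equivalent, so a reversal that merely re-orients an
arc within an equivalence class (e.g. `sex -> alcoholism` vs its reverse)
can be returned either way; structure-recovery reports therefore also track
whether a dependence was found in *either* orientation.

## Parameter fitting

CPTs are estimated as Dirichlet posterior means under a uniform
(BDeu-style) prior: with `r` child states, `q` parent configurations and
equivalent sample size ESS, every CPT cell receives pseudo-count
\(\alpha = \mathrm{ESS}/(rq)\) and
\[
\hat p_{jk} = \frac{N_{jk} + \alpha}{N_{j\cdot} + r\alpha}.
\]
The default ESS is 1, the common default of the discrete-network ecosystem
this design follows; it is exposed as a knob because the original analysis
does not state the value it used, which is one reason exact numeric
replication of its CPTs is impossible (the other being that the registry
data are private). Small ESS approaches maximum likelihood wherever counts
are nonzero; huge ESS shrinks every row toward uniform — both limits are
exercised in the tests. Fitting requires ESS > 0, which also guarantees
strictly positive CPTs, so no query can divide by zero after a refit.

## Exact inference

Risk queries condition on whatever subset of variables is observed and
marginalize the rest — this marginalization is exactly how the 5-, 6- and
7-predictor experiments drop the imaging variables from evidence. The
default engine enumerates the full joint (20,736 cells for the default
schema — small enough that approximation would only add error); a
factor-based variable-elimination engine is available for larger schemas
and doubles as an independent cross-check, with the two agreeing to 1e-9
on random networks in the test suite. Joint products accumulate in log
space whenever any CPT entry drops below 1e-12. Evidence with probability
zero raises an explicit error rather than returning NaN, because silent
NaN propagation would corrupt downstream AUCs.

## Validation protocol

Out-of-sample performance is assessed by repeated resampling with the
structure held fixed and only the CPTs refit per cycle (the published
protocol retrains "a conditional probabilities model" per sample against a
single presented structure). Four schemes are implemented: bootstrap
(training = 480 draws with replacement, testing = out-of-bag rows, so on
average \(1 - 1/e \approx 63.2\%\) of distinct patients train each cycle)
and hold-out 80:20, 90:10, 95:5. Whole-cohort cycles repeat until every
patient has been tested at least 30 times (the simplest reading of the
stopping rule; no per-patient targeting), each patient's score is the
arithmetic mean of their test-cycle probabilities, and the AUC is computed
on those averaged scores. The AUC interval is DeLong's normal-quantile
interval on the averaged scores — the default of the standard ROC tooling —
while `profile_probability_ci()` provides the percentile-over-cycles
alternative for single profiles, since the original tables do not state
their CI construction. Classification cutoffs maximize the Youden J
statistic with the rule *positive iff score ≥ cutoff*, ties toward the
smallest cutoff. One master seed drives everything: per-cycle child seeds
are derived deterministically and logged, making runs reproducible
bit-for-bit.

## The synthetic registry

The 480-patient registry behind the published analysis is not deposited;
what is public is its stratified count table (per class: total patients,
relapsed, AF-free). The generator (`build_ground_truth()`) is calibrated
against the packaged copy of those counts:

* **Marginals are matched exactly by construction.** Root CPTs use the
  printed frequencies; conditional CPTs anchor one column (e.g.
  P(smoking | male) = 0.36, chosen as a realistic sex effect) and solve
  the remaining column from the margin. Anchors live in
  `inst/extdata/generator_calibration.json`; solving infeasible targets
  errors rather than silently distorting.
* **Comorbidity CPTs are logistic.** Diabetes, high blood pressure and
  OSA get additive log-odds effects of their parents with the intercept
  solved numerically so the marginal matches the printed prevalence.
* **The outcome CPT is a calibrated surrogate.** A CPT over 7 parents has
  432 rows and is unidentifiable from one-dimensional margins, so the
  generator uses the smallest-complexity surrogate consistent with every
  printed margin: an additive (interaction-free) log-odds model whose
  coefficients are iteratively adjusted until the implied relapse rate
  within each parent class matches the stratified counts (e.g.
  P(relapse | OSA) = 35/50 = 0.70) to 1e-8.

A 200,000-row sample reproduces every calibration target to well within
1.5 percentage points (the audit is `calibration_report()`). What the
generator deliberately does **not** emulate: the outcome associations of
alcoholism, diabetes and high blood pressure (the printed graph gives them
no path into relapse, so their stratified imbalances in the real table are
unreachable by construction); follow-up durations and any time-to-event
structure; and real-data quirks such as measurement error, missingness or
residual confounding. Consequently, passing tests show the *pipeline* is
correct and well-behaved at realistic effect sizes — not that the published
AUC values would be recovered on the real registry. On synthetic cohorts
of the registry's size the qualitative finding does reproduce: mean AUC
ordering 7-predictor > 6-predictor > 5-predictor, with magnitudes that
depend on the generator's (clean, fully observed) dependencies and
typically sit somewhat above the published ones.

## Numerical choices and degenerate inputs

CPT rows must sum to 1 within 1e-9 and the enumerated joint to 1 within
1e-9. Hill-climbing accepts a move only if it gains more than 1e-9 in
score. One-class cohorts make AUC and Youden cutoffs undefined and raise
errors; bootstrap splits that produce an empty test set (possible only for
tiny cohorts) are retried and counted. Evidence assigning the query target
is rejected. Per-patient test counts accumulate exactly, and the stopping
rule is checked after whole cycles, so counts can exceed the minimum but
never undershoot it.

## Problem sizes in the shipped tests and benchmarks

The test suite and acceptance script exercise: structure recovery at
n = 20,000 over 10 seeds; parameter recovery at n = 500 vs 50,000 over 10
seeds; inference cross-checks on 100 random networks of up to 6 nodes;
validation on 480-row cohorts with the full four-scheme protocol at the
30-test minimum; and the predictor-set ordering as a mean over 20 protocol
seeds (run at a 10-test minimum per seed, since the ordering statistic
averages over seeds and does not need the tighter per-patient averaging). These sizes were chosen to make each property statistically
unambiguous at interactive runtimes.

## Limitations

The model is fully discrete; continuous or hybrid (conditional-Gaussian)
variants, imputation of missing *training* cells, approximate inference
and time-to-event modelling are out of scope. Profile-level probability
bands for fully specified 7-parent profiles can be very wide at n = 480 —
some parent configurations are observed a handful of times, exactly the
small-subsample caveat the original analysis acknowledges — and should be
read as honest uncertainty, not instability.
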