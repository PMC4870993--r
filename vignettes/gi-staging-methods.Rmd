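---
title: "Methods: severity staging and surgical outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity staging and surgical outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistage)
```

## The severity index

Visual-field-based staging systems grade structural and functional damage
but ignore how hard a glaucoma is to treat: a patient at 16 mmHg on one
drop and a patient at 24 mmHg off treatment may be equally challenging.
The glaucoma index (GI) used here multiplies three 4-level component
scores so that pressure, medication burden, and field damage all move the
stage:

* IOP points: `[0,20)` mmHg → 1, `[20,30)` → 2, `[30,40)` → 3,
  `[40,∞)` → 4. The bins are half-open so coverage is continuous; the
  integer clinical labels ("20–29 mmHg") are the inclusive integer ranges
  of these bins, and an IOP of exactly 40 scores 4.
* Medication points: ≤1 → 1, 2 → 2, 3 → 3, ≥4 → 4. Counts are whole
  numbers; fixed-combination drops count as recorded upstream.
* Visual-field points: mild 1, moderate 2, advanced 3, end-stage 4. The
  package consumes the stage as a categorical label; mapping perimetric
  indices (e.g. mean deviation) onto the four stages is the data
  producer's job.

GI = IOP points × medication points × VF points, range 1–64, and the
severity group is GI ≤ 4 → 1 (mild), 4 < GI ≤ 8 → 2 (moderate),
8 < GI ≤ 16 → 3 (advanced), GI > 16 → 4 (severe). All 64 attainable
products and their groups are verified against a brute-force scan in the
test suite. The supplied baseline IOP is treated as authoritative; the
package does not ask whether it was a single or washed-out measurement.

## Pipeline

`run_pipeline()` chains the stages: score the baseline table
(`score_baseline()`), build the per-group demographics report
(`demographics_table()`, Kruskal–Wallis for continuous rows, Pearson
chi-square for categorical rows), compute 12-month outcomes
(`compute_outcomes()`), screen covariates univariately and fit the
multivariate regression (`univariate_screen()`, `multivariate_fit()`),
and construct the survival analysis (`classify_events()`,
`km_estimate()`, `log_rank()`). Each stage is exported and usable on its
own; a thin command-line wrapper lives in `inst/cli/gistage.R`, and the
exported functions are the primary interface.

## Outcome definitions

The main outcome is the reduction of IOP at one year, baseline minus
follow-up (positive = improvement); medication reduction is computed the
same way. The 12-month value is taken from the visit closest to day 365
within ±90 days — a package convention, since clinical visits rarely land
on the anniversary; patients without a qualifying visit are excluded and
counted, mirroring the short-follow-up exclusion a registry analysis
would apply. Whether to use a window or last-observation-carried-forward
was an open choice; the window avoids manufacturing stable pressures for
patients who stopped attending.

## Regression

The univariate screen fits one OLS per covariate (age and cup/disc as-is,
Shaffer grade as ordinal 1–4, categoricals dummy-coded). Reference
levels: female, African American, primary open-angle glaucoma, phakic,
trabectome alone — the comparators a glaucoma audience expects.
`not_recorded` entries are treated as missing and dropped from model
rows, consistent with their exclusion from the chi-square tests.
Covariates with any term at p < 0.05 enter the multivariate model; 0.05
is the conventional reading of "statistically significant" and it
reproduces the pathway in which age and gender enter the final model but
lose significance there once severity is adjusted for.

The multivariate model enters the severity group as a single linear
ordinal term (1–4), not dummies, so it reports one coefficient per group
level. Two terms bypass the screen: the severity group (the exposure of
interest) and the surgery type. Always adjusting for surgery is a
deliberate design choice: combined phaco-trabectome versus trabectome
alone is the study's design variable, and its marginal (univariate)
association is heavily confounded by severity — the combined-surgery
share rises steeply with severity group, which can cancel a true negative
surgical effect in the unadjusted estimate and would otherwise let the
screen drop the variable the analysis exists to adjust for. No
multiple-testing correction is applied across screen rows, and no
mixed-effects or robust-variance machinery is used: cases are analysed
independently.

Rank-deficient designs abort with the collinear terms named rather than
silently dropping coefficients.

## Survival analysis

Surgical success is IOP ≤ 21 mmHg or at least a 20% reduction from
baseline, with no secondary glaucoma surgery. The success sentence can be
read two ways; the package adopts the standard glaucoma-literature
reading: a patient *fails* at the second of the first pair of consecutive
recorded visits, both strictly after day 90, that both violate the
criterion — the event is not established until confirmed. The
complementary single-visit reading is available via
`classify_events(rule = "single_visit")`. "After three months" means
strictly after day 90; consecutive means consecutive recorded visits,
whatever their spacing. A secondary surgery fails the patient at its
visit day regardless of pressure. Everyone else is censored at the last
visit day, administratively capped at day 365 for the 12-month figures
(`cap_day = NULL` retains full follow-up). Kaplan–Meier curves use the
product-limit estimator with failures preceding censorings at tied times,
and groups are compared with the k-sample log-rank chi-square on k−1
degrees of freedom. Both are computed via the survival package and are
checked against hand product-limit and observed-minus-expected
computations in the test suite.

## The synthetic cohort generator

Real registry data of this kind cannot be shared, so the generator exists
to make every downstream stage testable and to support parameter-recovery
validation. It emulates a 1340-case reference cohort: severity-group
shares 368/322/370/280, per-group demographic composition (gender,
ethnicity, diagnosis, lens status, Shaffer grade, surgery mix) from the
reference counts, per-group age, acuity, and cup/disc distributions
(truncated normals), and integer baseline pressures.

**Index components.** Each patient's (IOP bin, medication bin, VF stage)
triple is drawn from an independent component prior with decreasing
prevalence weights (0.55/0.25/0.13/0.07) conditioned exactly on the
assigned severity group — an O(1) equivalent of rejection sampling over
the 64 attainable combinations, which guarantees the recomputed group
always equals the assigned one. The decreasing weights encode that mild
component states dominate a microincisional-surgery population; a uniform
prior would fill the mild group with high-pressure patients no real
surgeon stages as mild.

**Latent reduction model.** The 12-month IOP reduction is

> reduction = c0 + 2.34·group + 3.81·hispanic + 2.91·pseudoexfoliation +
> 3.86·steroid − 1.29·phaco + 0.35·(baseline IOP − group mean) + ε

with ε normal and its per-group SD rescaled so the *marginal* per-group
SDs equal the configured 5.01/5.40/7.40/8.08 mmHg. The intercept c0 is
solved so the group-4 marginal mean equals 12.09 mmHg given the group-4
covariate mixture. Two aspects deserve emphasis:

* *Linear-in-group mean, anchored at the severe group.* The reference
  group means (3.57/5.34/7.75/12.09 mmHg) are convex in group, while the
  regression view of the same data summarises severity as one coefficient
  per level (2.34 mmHg). A single generative model cannot make all four
  marginal means and the linear coefficient hold simultaneously; the
  generator commits to the regression structure and anchors the severe
  group, whose mean is the headline result. Consequence: simulated
  groups 1–3 come out near 4.8/7.1/9.5 mmHg rather than the reference
  values — users comparing those should expect that gap.
* *Baseline-pressure dependence.* The 0.35 mmHg/mmHg term reflects
  outflow physiology: after trabecular meshwork removal the achievable
  pressure is bounded below by episcleral venous pressure, so higher
  preoperative pressures drop further. It is centered within group and
  independent of the regression covariates, so it changes no marginal
  group mean and biases no recovered coefficient; its practical role is
  that low-baseline mild patients sit comfortably under the 21 mmHg
  success bound, keeping spontaneous failure rates below the configured
  targets.

**Visits.** The schedule defaults to days 1, 7, 30, 90, 180, 270, 365 (a
convention — only the day-1 effect and month-scale follow-up are
documented for the reference cohort). The full reduction is present from
day 1 and stays flat, with per-visit tonometry noise (SD 1.5 mmHg,
rounded to 0.1 mmHg); medications taper linearly to a group-dependent
floor (60/50/35/25% of baseline), encoding the observation that more
severe patients shed more medications.

**Failures.** Only the 12-month failure proportions (7/16/18/26%) are
known for the reference cohort, so no hazard model is fitted — that would
over-claim. Failures that arise naturally from the honest trajectories
(low latent reduction, high baseline) are detected first with the same
event classifier users run; the generator then injects just enough
additional failures per group to reach `round(rate × n)`. Injected
failures are realised either as sustained pressure elevation overriding
the day-180/270 confirmation pair, or (with probability 0.15) as a
secondary-surgery flag at a random post-90-day visit. The confirmation
pair deliberately excludes the final scheduled visit so the day-365
endpoint measurement stays true to the latent model and the outcome
regression is uncontaminated. If natural failures alone already exceed a
group's target, the surplus is left in place — honest data are never
deleted — so realised rates can sit slightly above the configured value.

**What the generator does not emulate,** and hence what passing tests do
not show about real data: irregular visit spacing and missed visits,
bilateral eyes and within-patient correlation, medication class identity,
baseline-pressure imbalance between the surgery arms (the mechanism that
makes the *univariate* surgery coefficient strongly negative in real
cohorts; in simulated data that unadjusted estimate is near zero because
severity confounding and the true negative effect cancel), measurement
drift, and informative censoring. Recovery of the configured effects
demonstrates the estimation pipeline is correct, not that the generative
model is a faithful portrait of clinical reality.

## Numerical choices and degenerate inputs

* Kruskal–Wallis on identical values returns H = 0, p = 1 (the tie
  correction is otherwise undefined); p-values use the chi-square
  approximation, not permutation.
* Chi-square uses Pearson's statistic without continuity correction and
  refuses tables with an all-zero margin.
* Percentages in the demographics report are rounded to whole numbers;
  they always recompute from the reported counts.
* OLS runs through `stats::lm`; rank deficiency is an error, never a
  silent drop.
* Empty cohorts flow through the whole pipeline producing schema-valid
  empty outputs.
* With a fixed seed all data outputs (CSV/JSON) are byte-identical across
  runs; the KM figure (PDF) embeds a device creation date and is excluded
  from that guarantee.

## Problem sizes

The test suite validates arithmetic and oracle equivalence on instances
of at most a few dozen rows, distributional calibration on cohorts of
2000–4000, and parameter recovery on a single shared 5000-patient
simulation — sizes at which Monte-Carlo error is a small fraction of the
effects being recovered while the whole suite runs in well under a
minute. The acceptance script uses the same 5000-patient default.

## Known limitations

The staging thresholds are conventions inherited from the index
definition, not fitted quantities. The generator's additive,
homoscedastic-within-group error model is a simplification; real
reduction distributions are right-skewed. The event classifier assumes
per-patient visit streams are strictly ordered and complete as recorded;
it does not impute missed confirmations. None of the analyses model
eye-level clustering, competing risks, or time-varying covariates.
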