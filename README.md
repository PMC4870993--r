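# gistage

Severity staging and surgical outcome analysis for open-angle glaucoma
cohorts treated with ab interno trabeculectomy (trabectome), alone or
combined with phacoemulsification.

Classical glaucoma staging grades visual-field damage but ignores how
resistant a glaucoma is to treatment. `gistage` implements a composite
**glaucoma index (GI)** that multiplies three 4-level component scores —
baseline intraocular pressure (IOP), medication burden, and visual-field
(VF) stage:

    GI = VF points × medication points × IOP points,   GI ∈ {1, …, 64}

with IOP binned at <20 / 20–29 / 30–39 / ≥40 mmHg, medications at ≤1 / 2 /
3 / ≥4, and VF staged mild / moderate / advanced / end-stage, each worth
1–4 points. Patients are staged into severity groups
GI ≤ 4 (mild), 4 < GI ≤ 8 (moderate), 8 < GI ≤ 16 (advanced), GI > 16
(severe).

On top of the index the package provides the full outcomes pipeline used
in severity-stratified surgical audits:

* **Baseline comparison** — per-group demographics with Kruskal–Wallis
  (continuous) and Pearson chi-square (categorical) tests.
* **Outcome regression** — 12-month IOP reduction per patient, a
  univariate screen over clinical covariates, and a multivariate OLS with
  the severity group as a linear ordinal term.
* **Survival analysis** — rule-based event construction (failure =
  IOP > 21 mmHg *and* < 20% reduction at two consecutive visits after
  three months, or secondary glaucoma surgery), Kaplan–Meier curves per
  group, and the k-sample log-rank test.
* **Synthetic cohorts** — a calibrated generator
  (`generate_cohort()`) emulating a 1340-case reference registry, so the
  entire pipeline is testable and demonstrable without patient data.

## Worked example

Score a few patients:

```r
library(gistage)
gi_score(iop = c(18, 25, 34, 45), meds = c(1, 2, 3, 5),
         vf_stage = c("mild", "moderate", "advanced", "end_stage"))
#> # A tibble: 4 × 5
#>   iop_points med_points vf_points    gi gi_group
#>        <int>      <int>     <int> <int>    <int>
#> 1          1          1         1     1        1
#> 2          2          2         2     8        2
#> 3          3          3         3    27        4
#> 4          4          4         4    64        4
```

Note the multiplicative scale: a patient at 34 mmHg on three medications
with advanced field loss (GI 27) is already in the severe group.

Simulate a registry-sized cohort and run the analysis:

```r
cohort   <- generate_cohort(cohort_config(n_patients = 1340, seed = 42))
outcomes <- compute_outcomes(cohort, quiet = TRUE)
round(tapply(outcomes$iop_reduction_12mo, outcomes$gi_group, mean), 2)
#>     1     2     3     4
#>  4.60  6.64 10.31 11.58
```

Mean pressure reduction rises with severity group — severe patients gain
the most from meshwork removal. The screen-then-fit regression quantifies
that per level, holding demographics constant:

```r
screen <- univariate_screen(outcomes, cohort$baseline)
fit <- multivariate_fit(outcomes, cohort$baseline,
                        covariates = attr(screen, "selected"))
fit
#> <gi_fit> multivariate OLS, n = 1284
#> # A tibble: 14 × 5
#>    term                            estimate std_error statistic  p_value
#>  1 (Intercept)                       3.11       1.14     2.72   6.65e- 3
#>  2 gi_group                          2.29       0.180   12.7    5.46e-35
#>  3 surgeryphaco_trabectome          -1.37       0.385   -3.55   4.03e- 4
#>  6 ethnicityhispanic                 2.95       1.11     2.65   8.16e- 3
#>  8 diagnosispseudoexfoliation        2.88       0.586    4.91   1.04e- 6
#> 10 diagnosissteroid                  5.04       0.661    7.63   4.76e-14
#>  # … remaining non-significant terms omitted here for brevity
```

Each severity level adds ~2.3 mmHg of reduction; combined
phaco-trabectome reduces pressure ~1.4 mmHg less than trabectome alone;
Hispanic ethnicity, pseudoexfoliation, and steroid-induced glaucoma gain
extra reduction relative to their reference levels (African American,
primary open-angle glaucoma).

Surgical success over the first year:

```r
events <- classify_events(cohort)
km_estimate(events)
#> <gi_km> Kaplan-Meier surgical-success curves
#>   12-month survival by severity group:
#>     group 1: 93.0%
#>     group 2: 83.9%
#>     group 3: 81.9%
#>     group 4: 74.1%
log_rank(events)$p_value
#> 1e-09  (chi-square 44.7 on 3 df)
```

`run_pipeline(out_dir, simulate = TRUE, seed = 42)` runs all of the above
end to end and writes every table, the survival curves, a KM figure, and
a reproducibility manifest. A thin command-line wrapper with the same
stages lives in `inst/cli/gistage.R`.

## Package layout

* `R/gi_index.R` — component points, composite score, group thresholds
* `R/simulate.R`, `R/config.R` — synthetic cohort generator and its
  calibration
* `R/baseline_stats.R` — demographics table, Kruskal–Wallis, chi-square
* `R/outcomes.R` — 12-month outcomes, univariate screen, multivariate OLS
* `R/survival.R` — event construction, Kaplan–Meier, log-rank
* `R/pipeline.R` — end-to-end runner with manifest
* `vignettes/gi-staging-methods.Rmd` — the model, its assumptions, every
  tunable parameter, and the generator's design rationale
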