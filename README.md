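# pahkin — urinary PAH biomarker toxicokinetics from spot-urine sampling

`pahkin` analyses repeated-measures spot-urine biomonitoring studies of
occupational PAH exposure, of the kind used to characterise what firefighting
instructors absorb during live fire training: a cohort of subjects each
completes several training sessions, collecting urine at nine scheduled times
around each session (unscheduled voids are pooled into the next scheduled
sample), and urinary metabolites — 1,2-dihydroxynaphthalene (DHN), 1- and
2-hydroxynaphthalene (1-NAP, 2-NAP), 1-hydroxypyrene (1-PYR) — are assayed
together with creatinine.

The package provides, as separately usable stages:

* **Synthetic data** — a void-level generator with first-order
  absorption/elimination (Bateman) kinetics per analyte, background
  excretion, creatinine and urine-flow variability, assay noise and LOD
  censoring, under the study's 6 subjects × 5 sessions × 9 samplings
  protocol (`simulate_study()`, `params.paper.yaml`).
* **Preprocessing** — volume-weighted pooling of unscheduled voids,
  LOD/2 substitution of censored values, creatinine adjustment
  (µg/L → µg/g), the 0.3–3.0 g/L creatinine inclusion filter (bounds
  inclusive) and a full sample accounting report (`preprocess_voids()`).
* **Descriptives** — per-window concentration percentiles, within-set
  relative changes, naphthalene-metabolite proportions, Pearson correlations
  of log concentrations (`summarize_by_window()`, `relative_change()`,
  `metabolite_proportions()`, `log_pearson()`).
* **Elimination kinetics** — per-set peak location, decay records
  `y = ln(C − C0)` against time since peak, and the mixed-effects decay model

  C = C0 + B·e^{λt} + ε,

  fitted on the log scale as a linear mixed model with per-biomarker fixed
  intercepts and slopes, correlated participant-level random intercept and
  slope, a session-within-participant random intercept, and AR(1) residual
  correlation, estimated by REML with an in-package likelihood
  (`fit_eq1_mixed()`). Half-lives are ln 2 / (−λ̂) with transformed
  confidence intervals (`derive_half_lives()`), and `time_to_baseline()`
  projects the return from peak to pre-exposure levels.
* **Pipeline** — `run_pipeline()` chains the stages and writes versioned,
  seeded CSV/JSON artifacts plus a markdown report;
  `inst/scripts/pahkin-cli.R` exposes the same stages as shell subcommands.

## Worked example

```r
library(pahkin)

v <- simulate_study(study_design(), paper_analytes(), seed = 42)
prep <- preprocess_voids(v, expected = 270)
prep$accounting
#> $expected [1] 270    $collected [1] 270
#> $included [1] 250    $excluded_creatinine [1] 20   $missing [1] 0

recs <- build_decay_records(prep$samples, c("DHN", "NAP1", "NAP2", "PYR1"))
fit_eq1_mixed(recs)
#> <eq1_fit> REML, 564 records, 6 participants, converged
#>   sigma = 0.6594, phi = 0.589, logLik = -497.040
#>   DHN   lambda -0.11554 (se 0.01299)  t1/2  6.00 h [4.57, 8.72]
#>   NAP1  lambda -0.12657 (se 0.01302)  t1/2  5.48 h [4.26, 7.67]
#>   NAP2  lambda -0.14608 (se 0.01347)  t1/2  4.74 h [3.78, 6.38]
#>   PYR1  lambda -0.09986 (se 0.01479)  t1/2  6.94 h [4.92, 11.79]
```

270 scheduled samples were pooled, adjusted and filtered (20 fell outside
the creatinine band at this seed); the fitted elimination slopes translate
into half-lives of roughly 6.0, 5.5, 4.7 and 6.9 h at this single seed,
scattering around the generator's configured truths of 6.6, 6.2, 5.2 and
7.7 h (the confidence intervals cover them). A complete run with all
artifacts:

```r
res <- run_pipeline("run-directory", seed = 1)
res$half_lives
```

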