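# resq — residual-based resilience quantification for stressor-exposure surveys

`resq` implements an outcome-based resilience analysis for cross-sectional
survey data, of the kind used to study who stayed mentally healthy through
the COVID-19 lockdowns. It is aimed at biostatisticians and psychiatric
epidemiologists who have (or want to simulate) tabular survey records with
symptom items, stressor checklists and psycho-social scale scores.

## The method

Resilience is treated as an *outcome* — good mental health despite stressor
exposure — not a trait score. Given a GHQ-12 symptom total
*P* (twelve items scored 0–3, range 0–36) and a severity-weighted
stressor-exposure index *E* (sum of 1–5 severity ratings over endorsed
items; general index *E*<sub>G</sub> over 11 item classes, crisis-specific
*E*<sub>S</sub> over 29 items, combined index
*E*<sub>C</sub> = (*z*<sub>G</sub> + *z*<sub>S</sub>)/2), the sample's
least-squares regression of *P* on *E* is the normative reactivity curve,
and each participant's resilience is the **inverse residual**

> RES = P̂(E) − P

so under-reactive participants (fewer symptoms than predicted for their
exposure) score positive. RES has mean zero and zero correlation with *E*
by construction — exposure differences are corrected for inherently.

Around this core the package provides the full analysis chain:

* record cleaning (five ordered removal rules) and complete/incomplete
  classification;
* covariate screening by likelihood-ratio tests at *p* < 0.2;
* nine directed factor hypotheses, each in its own covariate-adjusted
  regression with 99% CIs and a Bonferroni comparison threshold 0.01/9;
* Baron–Kenny mediation with asymptotic-normal (Sobel) indirect-effect CIs;
* L1-penalized factor ranking with 10-fold cross-validation, the
  one-standard-error rule, deviance ratios, and repeated-run selection
  stability;
* subgroup interaction models with per-level effects, a sign-consistency
  audit, and per-level penalized ranks;
* a synthetic-cohort generator with known ground truth, so every stage has
  a known-answer test without any data download.

See the vignette (`vignettes/resilience-quantification.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

```r
library(resq)

cfg <- cohort_config(n_participants = 4000)   # study-condition defaults
cohort <- simulate_cohort(cfg, seed = 1)
cleaned <- clean_responses(cohort$responses)
cleaned$report
#> <cleaning_report>
#>   registered: 4000
#>   removed:    0
#>   valid:      4000
#>   incomplete: 599 (15.0%)
#>   complete:   3401

scored <- compute_resilience(score_participants(cleaned$participants))
analysed <- scored[!is.na(scored$res_c), ]

test_all_factors(analysed, "res_c", covariates = c("age", "gender"))
#> # A tibble: 9 × 8
#>   factor   beta     se         p  lower  upper delta_adj_r2     n
#> 1 pas     1.88  0.0703 1.24e-142  1.69   2.06        0.173   3401
#> 2 pss     1.04  0.0777 1.33e- 39  0.836  1.24        0.0495  3401
#> ...
#> 7 neu    -1.41  0.0747 9.97e- 76 -1.60  -1.22        0.0948  3401
```

Every factor shows its hypothesized sign (all positive, neuroticism
negative), with `delta_adj_r2` the variance each explains beyond the
covariates. Mediation of the support–resilience association by appraisal
style:

```r
baron_kenny(analysed, "pss", "pas", "res_c", covariates = c("age", "gender"))
#> <mediation_result> pss -> pas -> res_c (n = 3401)
#>   a = 0.4859 (se 0.0156), b = 1.8016 (se 0.0796)
#>   c = 1.0359, c' = 0.1605
#>   indirect a*b = 0.8754 (se 0.0478), 99% CI [0.7522, 0.9985]
```

The indirect path `a*b` is significantly positive (its 99% CI excludes 0),
and `c = c' + a*b` exactly. Ranking the factors jointly:

```r
lasso_rank(analysed, "res_c", covariates = c("age", "gender"),
           runs = 20, seed = 1)
#> <lasso_result> n = 3401
#>   lambda_min = 0.03186, lambda_opt (1-SE) = 0.29710
#>   deviance ratio at lambda_opt = 0.240
#>   factor ranks:
#>     1. rec  beta = +0.6555  (selected in 100% of runs)
#>     2. pas  beta = +0.5833  (selected in 100% of runs)
#>     3. neu  beta = -0.3547  (selected in 100% of runs)
#>     ...
#>     9. bcs  beta = +0.0000  (selected in 5% of runs)
```

Stress recovery ranks first; the factors jointly explain 24% of the
resilience variance (deviance ratio); the weakest factor (behavioral
coping) is the only one not reliably selected across repeated runs.
`run_pipeline()` chains all stages — cleaning report, stressor
descriptives, screening, factor fits, mediation, ranking, subgroup tables —
into one reproducible bundle, and `write_report()` serializes it to
CSV/JSON.

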