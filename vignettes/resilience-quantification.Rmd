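---
title: "Residual-based resilience quantification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-based resilience quantification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The outcome model

Outcome-based resilience is *maintained mental health despite stressor
exposure*. Neither symptoms nor their absence measure resilience on their
own: a symptom-free person who experienced nothing adverse has demonstrated
nothing. `resq` therefore relates a symptom total $P$ (GHQ-12, twelve items
scored 0–3, range 0–36) to a stressor-exposure index $E$ and takes the
sample's least-squares regression of $P$ on $E$ as the *normative reactivity
curve*: the symptom level expected at a given exposure. A participant's
resilience is the **inverse residual**

$$\mathrm{RES} = \hat{P}(E) - P,$$

so someone with *fewer* symptoms than predicted for their exposure scores
*positive*. Because the curve is an intercept-carrying least-squares fit,
RES has mean zero over the fitting sample and — for the linear form — zero
sample correlation with $E$: the measure inherently corrects for individual
differences in exposure. Both properties are asserted to $10^{-8}$ in the
test suite.

Exposure comes in three flavours. $E_G$ and $E_S$ are severity-weighted sum
counts over 11 general and 29 crisis-specific stressor items (each endorsed
item contributes its 1–5 severity rating; unendorsed items contribute 0),
and $E_C$ averages the z-scores of the two: $E_C = (z_G + z_S)/2$, with
z-normalization over the analysed (complete-data) sample using the $n-1$
standard deviation. Each index yields its own resilience score
(`res_c`, `res_g`, `res_s`) from a separately fitted curve.

### Choices made where the design was open

* **Curve form.** The default is linear. No curvature is described for the
  normative relationship, and a linear fit is the weakest assumption under
  which the residual construction behaves as intended; a quadratic form is
  available behind `form = "quadratic"` for sensitivity analysis.
* **Sign convention.** `RES = predicted − observed`. Every downstream sign
  (factor hypotheses, mediation paths, subgroup tables) depends on this, so
  it is fixed package-wide and documented on `residual_resilience()`.
* **GHQ-12 scoring.** Plain Likert 0–3 per item. The bimodal 0-0-1-1
  scoring has maximum 12 and is incompatible with the 0–36 range the index
  is defined on.
* **Severity weighting.** Interpreted as the sum of severities over
  endorsed items, not count × mean severity; the two only coincide when all
  severities are equal, and the sum is the natural reading of a weighted
  sum count.
* **Complete cases only.** Normative curves, and hence resilience scores,
  are computed for participants with complete stressor and symptom blocks;
  incomplete records are carried through cleaning but excluded from every
  analysis requiring RES. No imputation is attempted.
* **Covariates stay out of the normative curve.** Exposure alone defines
  normative reactivity; socio-demographic adjustment happens in the
  downstream regressions, where it can be screened and reported.

## The analysis chain

**Cleaning.** Five removal rules, applied in a fixed order with first-match
attribution: invalid age (non-parseable, negative, or above 120), underage,
missing initial socio-demographics, income on the prefinal scale, missing
follow-up socio-demographics. First-match attribution makes per-rule counts
well defined when a record violates several rules. A malformed field is a
removal reason, never an exception. Completeness then hinges exactly on the
fields RES needs — all stressor endorsements, severities for endorsed items,
and all twelve symptom items; optional free-text questions never count
(treating them as required is a documented way to get completeness wrong).

**Screening.** Each candidate covariate is tested univariately against RES
with a likelihood-ratio test ($2\Delta\ell$ against $\chi^2$ with one df per
added indicator term) and retained at $p < 0.2$ — deliberately permissive,
since the cost of a spurious covariate in the adjusted models is small
compared to omitted confounding. Categorical covariates are treatment-coded
with the most frequent level as reference.

**Directed hypotheses.** Each of the nine psycho-social factors (positive
appraisal style `pas`, perceived social support `pss`, crisis-related
support increase `css`, optimism `opt`, self-efficacy `gse`, stress
recovery `rec`, neuroticism `neu` — the one negative hypothesis —
behavioral coping `bcs`, and crisis-specific positive appraisal `pac`) is
tested in its own multiple regression `RES ~ covariates + factor`, with a
99% Wald (t-quantile) CI, a two-tailed p-value, and the adjusted-$R^2$
increase over the covariates-only model. The family-wise comparison
threshold is Bonferroni: $0.01/9 \approx 0.0011$.

**Mediation.** The two preregistered paths (support → appraisal style →
resilience; appraisal style → recovery → resilience) follow the Baron–Kenny
three-regression scheme, all regressions covariate-adjusted — the
covariate-adjusted framework is used consistently, and for nested linear
fits the decomposition $c = c' + ab$ then holds exactly. The indirect
effect's CI uses the first-order asymptotic-normal (Sobel) standard error
$\sqrt{a^2 se_b^2 + b^2 se_a^2}$; the second-order term is available via
`second_order = TRUE`. A bootstrap CI is used as an independent cross-check
in the tests, not as the implementation.

**Penalized ranking.** All factors and retained covariates enter one
Gaussian lasso on a standardized design (so coefficient magnitudes are
comparable, which the ranking requires). The penalty grid has 100
log-spaced points from $\lambda_{max}$ (smallest penalty with an all-null
model) down by $10^{-3}$. The penalty is chosen by 10-fold
cross-validation with the one-standard-error rule — the *largest* penalty
whose CV error is within one SE of the minimum, favouring the simplest
comparable model. Fold counts and the grid are conventional defaults; the
path itself is solved by glmnet's coordinate descent, while fold
construction, 1-SE selection, the deviance ratio
($1 - RSS/RSS_0$, clipped to $[0,1]$), stability repeats and ranking are
implemented and oracle-tested in this package. Stability selection repeats
the whole CV + 1-SE pipeline with re-randomized folds (800 runs at full
scale; row bootstrap optional) and reports per-term selection frequencies.
Ranks order factors by $|\beta|$ at the selected penalty, ties broken by
the canonical factor order and flagged when degenerate.

**Subgroups.** For each socio-demographic covariate (gender, age bins
18–30/31–45/46–60/61+, country, eight income bands, education bins
<13/13–16/17–20/21+, mental-health diagnosis) and each factor, an
interaction model `RES ~ covariates + group + factor + factor:group` gives
per-level slopes (main effect plus interaction contrast, delta-method SE)
and an interaction-block LR test at the study-wide two-tailed α = 0.01.
Levels excluded for small size (gender "diverse", diagnosis
"not assessed") drop out with the sample reduced. The sign-consistency
audit counts minority-sign cells within each (covariate, factor) group and
CI zero-crossings over all level × factor cells. Per-level penalized ranks
re-run the lasso within each level with independent per-level penalty
selection (a shared penalty would couple the levels' models for no clear
benefit); levels smaller than the fold count are skipped with a warning.

## The synthetic cohort and what it does (not) show

No real survey data ship with the package. The generator
(`cohort_config()` + `simulate_cohort()`) produces cohorts with the
statistical structure the analysis assumes, plus the ground truth needed
for known-answer tests:

* **Symptom model.** $P = b_0 + b_1 E_{true} - \sum_k w_k F_k +
  \varepsilon$, $\varepsilon \sim N(0, \sigma)$, clamped to $[0, 36]$ and
  discretized onto twelve 0–3 items by equal-share largest-remainder
  allocation, so the item total equals the rounded continuous target.
  Additive linearity is the weakest structure under which every analysis in
  the chain is a consistent estimator of its target.
* **Factors.** Standardized latent scores from a 9×9 correlation matrix,
  after which appraisal style is structurally overwritten as
  $a_1 \cdot \mathrm{pss} + \sqrt{1-a_1^2}\,\epsilon$ and recovery as
  $a_2 \cdot \mathrm{pas} + \sqrt{1-a_2^2}\,\epsilon$, installing the two
  mediation paths. The disturbance reuses the factor's own correlated draw,
  so marginal variances are approximately (not exactly) one when the base
  matrix links the overwritten factor to its cause; recovery tests
  therefore compute implied truths from the generator equations rather
  than assuming unit variances.
* **Stressors.** Bernoulli endorsement per item with ordinal 1–5
  severities; a shared per-participant propensity (SD 0.8 on the logit
  scale) induces the positive correlation between general and specific
  exposure observed in real cohorts. Item intercepts are calibrated by
  Gauss–Hermite quadrature so *marginal* endorsement equals the configured
  prevalence despite the propensity. Severities exist only for endorsed
  items.
* **Defaults are the study conditions.** 18,695 valid records; 15.5%
  missing the trailing stressor block; headline prevalences 93/90/88/86%
  (specific) and 83/62/61% (general); mean symptom burden 15.5 points with
  weights and noise (σ = 4) set so the factors jointly explain roughly a
  quarter of the resilience variance and the strongest factors are stress
  recovery and crisis-specific appraisal, with behavioral coping weakest.
  Defective records are injected only on request (`invalid_counts`),
  because only the total removed — not per-rule counts — is publicly known
  for the motivating study; each injected defect is tagged in the ground
  truth so cleaning can be audited defect by defect.
* **Seed discipline.** One seed, split into labelled streams per
  sub-generator (covariates, factors, stressors, symptoms, missingness,
  injection), so switching one component on or off never perturbs the
  others, and identical (config, seed) reproduces the cohort bit for bit.

What passing tests on this cohort *show*: the estimators recover known
weights, paths and orderings; the CIs hold nominal coverage; cleaning and
completeness arithmetic reconcile; the machinery (1-SE rule,
soft-thresholding, deviance ratio, rank audit) matches closed forms. What
they *do not show*: anything about non-linear exposure–symptom
relationships, informative missingness, response styles varying by country
or language, item-level measurement error in the factor scales, or sampling
bias — none of which the generator emulates. Covariates are sampled
independently of symptoms, so covariate screening operates at its null in
generated data.

## Numerical notes

* z-scores use the $n-1$ denominator throughout; exposure z-normalization
  is recomputed on the analysed sample, never reused from another subset.
* The GHQ discretization error is at most half a point on the total;
  noise-free test limits account for it explicitly.
* Lasso solutions are verified against the coordinate-wise soft-threshold
  closed form on orthonormal designs at $10^{-8}$, with the solver's
  convergence threshold tightened to $10^{-12}$.
* Degenerate inputs fail loudly and early: constant exposure, zero-variance
  responses, rank-deficient designs (offending terms named), single-level
  covariates, a mediator identical to its predictor, unknown defect-class
  names (valid classes listed).
* Test and acceptance suites run at reduced but honest sizes: recovery at
  n = 5,000 over 100 seeds, coverage at n = 2,000 over 1,000 replicates,
  stability at 50 runs on n = 5,000, the sign-flip audit at n = 10,000 over
  20 seeds, and full-scale (26,348-record) cleaning arithmetic once. These
  are the package's chosen verification sizes; the pipeline itself has no
  size limits.

## Limitations

Cross-sectional residual-based resilience cannot separate reactivity from
recovery, inherits any retrospective-report bias in its inputs, and — being
defined relative to the sample's own normative curve — is a *relative*
measure: scores are not comparable across separately fitted samples. The
stress-recovery factor is semantically close to the symptom instrument
itself, which inflates its association with the outcome; the package ranks
factors as given and leaves that interpretive caveat to the analyst.
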