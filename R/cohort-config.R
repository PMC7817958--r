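# Generator configuration: study-condition defaults for the synthetic cohort.

#' Resilience-factor abbreviations
#'
#' The nine psycho-social resilience factors carried through every analysis:
#' positive appraisal style (`pas`), perceived social support (`pss`),
#' perceived increase in social support during the crisis (`css`), optimism
#' (`opt`), general self-efficacy (`gse`), perceived good stress recovery
#' (`rec`), neuroticism (`neu`, hypothesized negative), behavioral coping
#' style (`bcs`) and positive appraisal specifically of the Corona crisis
#' (`pac`).
#'
#' @return Character vector of the nine factor names.
#' @export
resilience_factors <- function() {
  c("pas", "pss", "css", "opt", "gse", "rec", "neu", "bcs", "pac")
}

#' General (11-class) and crisis-specific (29-item) stressor names
#'
#' @return Named list with `general` (11 items) and `specific` (29 items).
#' @export
stressor_items <- function() {
  list(
    general = c(
      "negative_political_events", "family_conflicts", "work_stress",
      "financial_problems", "physical_illness_self", "mental_health_problems",
      "physical_illness_close", "separation_from_loved_one",
      "housing_problems", "death_of_loved_one", "other_general"
    ),
    specific = c(
      "media_coverage", "leisure_restricted", "loss_social_contact",
      "restricted_leave_home", "uncertainty_future", "cancelled_events",
      "travel_restrictions", "shopping_restrictions", "conflicting_information",
      "home_office", "infection_fear_close", "risk_group_close",
      "distance_rules_stress", "infection_fear_self", "boredom",
      "supply_shortage", "income_loss", "postponed_medical_care",
      "job_insecurity", "risk_group_self", "crowded_household",
      "helping_others_burden", "childcare_problems", "covid_symptoms_self",
      "covid_close_infected", "quarantine_self", "hospital_visit_restricted",
      "funeral_restricted", "other_specific"
    )
  )
}

default_stressor_prevalence <- function() {
  items <- stressor_items()
  general <- c(0.83, 0.62, 0.61, 0.35, 0.30, 0.33, 0.28, 0.25, 0.15, 0.08, 0.20)
  specific <- c(
    0.93, 0.90, 0.88, 0.86, 0.70, 0.70, 0.65, 0.60, 0.55,
    0.55, 0.55, 0.50, 0.50, 0.45, 0.45, 0.40, 0.30, 0.25,
    0.25, 0.25, 0.20, 0.20, 0.18, 0.15, 0.12, 0.12, 0.10,
    0.04, 0.15
  )
  c(
    setNames(general, paste0("gs_", items$general)),
    setNames(specific, paste0("cs_", items$specific))
  )
}

default_factor_correlation <- function() {
  f <- resilience_factors()
  r <- matrix(0.10, 9, 9, dimnames = list(f, f))
  block <- c("pas", "opt", "gse", "rec")
  r[block, block] <- 0.40
  r["neu", ] <- r[, "neu"] <- -0.10
  r["neu", block] <- r[block, "neu"] <- -0.35
  r["pas", "pac"] <- r["pac", "pas"] <- 0.35
  diag(r) <- 1
  r
}

# Symptom points per SD of factor (negated inside the symptom model, so a
# positive weight is protective). Magnitudes are set so factors jointly
# explain roughly a quarter of the resilience variance and the symptom SD
# lands near 6; the ordering puts stress recovery first, then crisis-specific
# positive appraisal and (harmful) neuroticism, with behavioral coping
# weakest.
default_factor_weights <- function() {
  c(
    pas = 0.39, pss = 0.32, css = 0.21, opt = 0.42, gse = 0.35,
    rec = 0.64, neu = -0.53, bcs = 0.14, pac = 0.57
  )
}

default_covariate_distributions <- function() {
  list(
    gender = c(male = 0.240, female = 0.752, diverse = 0.008),
    age = list(
      breaks = list(c(18, 30), c(31, 45), c(46, 60), c(61, 80)),
      probs = c(0.40, 0.31, 0.21, 0.08)
    ),
    country = c(
      Belgium = 0.05, Germany = 0.30, `Hong Kong` = 0.04, Hungary = 0.05,
      Italy = 0.07, Netherlands = 0.08, Poland = 0.06, Serbia = 0.04,
      Other = 0.31
    ),
    income = c(
      "0-4999" = 0.13, "5000-9999" = 0.13, "10000-14999" = 0.12,
      "15000-24999" = 0.15, "25000-49999" = 0.20, "50000-74999" = 0.12,
      "75000-99999" = 0.07, "100000+" = 0.08
    ),
    education = list(
      breaks = list(c(8, 12), c(13, 16), c(17, 20), c(21, 25)),
      probs = c(0.15, 0.35, 0.33, 0.17)
    ),
    diagnosis = c(yes = 0.21, no = 0.71, not_assessed = 0.08)
  )
}

#' Names of the record-defect classes exercised by the cleaning rules
#'
#' One class per removal rule, in the order the rules are applied:
#' non-parseable/out-of-range age, underage, missing initial
#' socio-demographics, income reported on the prefinal scale, and missing
#' follow-up socio-demographics.
#'
#' @return Character vector of the five class names.
#' @export
invalid_record_classes <- function() {
  c(
    "invalid_age", "underage", "missing_initial_sociodemo",
    "prefinal_income", "missing_followup_sociodemo"
  )
}

#' Synthetic-cohort generator configuration
#'
#' Builds the configuration of the survey-cohort generator. Defaults emulate
#' the study conditions of a large lockdown-period survey: 18,695 valid
#' records with 15.5% missing the trailing stressor block, the most frequent
#' crisis-specific stressor endorsed by 93% of participants (media coverage,
#' then 90%, 88%, 86%) and the most frequent general stressor by 83%
#' (negative political events, then 62%, 61%), a mean symptom burden around
#' 15.5 GHQ-12 points, and mediation paths from perceived social support to
#' positive appraisal style and from positive appraisal style to stress
#' recovery.
#'
#' The symptom-generating model is additive-linear:
#' `P = b0 + b1 * E_true - sum_k w_k * F_k + N(0, noise_sd)`,
#' discretized onto twelve 0-3 items, where `E_true` is the average of the
#' z-scored severity-weighted stressor sums and `F_k` are standardized latent
#' factor scores.
#'
#' @param n_participants Number of genuine (non-injected) records.
#' @param stressor_prevalence Named probability per stressor item
#'   (11 general `gs_*` + 29 specific `cs_*`).
#' @param severity_probs Probability vector over ordinal severities 1-5
#'   (recycled per item) or a 40 x 5 matrix with rows per item.
#' @param factor_correlation 9 x 9 symmetric positive-definite correlation
#'   matrix of the latent factor draw.
#' @param factor_weights Named weight per factor in the symptom model
#'   (symptom points per factor SD, entering with a minus sign).
#' @param mediation_paths Named numeric: `pss_pas` (support to appraisal
#'   style) and `pas_rec` (appraisal style to recovery) path coefficients.
#' @param exposure_slope Slope `b1` of true exposure in the symptom model.
#' @param baseline_symptoms Intercept `b0` (expected GHQ-12 total at average
#'   exposure and average factor levels).
#' @param noise_sd SD of the Gaussian symptom noise.
#' @param exposure_propensity_sd SD of a per-participant latent endorsement
#'   propensity shared by all stressor items (induces the positive
#'   correlation between general and specific exposure seen in real data;
#'   set 0 for independent endorsement).
#' @param covariate_distributions Categorical distributions of the
#'   socio-demographic covariates; see `default_covariate_distributions`
#'   in the package source for the expected structure.
#' @param missingness Probability a participant leaves the trailing stressor
#'   block unanswered (drives the complete/incomplete split).
#' @param invalid_counts Named nonnegative counts of injected defective
#'   records per cleaning-rule class (see [invalid_record_classes()]).
#' @param seed Default RNG seed used by [simulate_cohort()].
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- cohort_config(n_participants = 500)
#' cfg$stressor_prevalence[["cs_media_coverage"]]
#' @export
cohort_config <- function(n_participants = 18695,
                          stressor_prevalence = default_stressor_prevalence(),
                          severity_probs = c(0.20, 0.25, 0.25, 0.20, 0.10),
                          factor_correlation = default_factor_correlation(),
                          factor_weights = default_factor_weights(),
                          mediation_paths = c(pss_pas = 0.4, pas_rec = 0.5),
                          exposure_slope = 3.0,
                          baseline_symptoms = 15.5,
                          noise_sd = 4.0,
                          exposure_propensity_sd = 0.8,
                          covariate_distributions = default_covariate_distributions(),
                          missingness = 0.155,
                          invalid_counts = setNames(
                            integer(length(invalid_record_classes())),
                            invalid_record_classes()
                          ),
                          seed = 1L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 1 || n_participants != round(n_participants)) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  stopifnot_prob(stressor_prevalence, "stressor_prevalence")
  if (length(stressor_prevalence) != 40L) {
    stop("`stressor_prevalence` must cover all 40 stressor items",
         call. = FALSE)
  }
  if (is.matrix(severity_probs)) {
    if (ncol(severity_probs) != 5L || nrow(severity_probs) != 40L) {
      stop("`severity_probs` matrix must be 40 x 5", call. = FALSE)
    }
    sev <- severity_probs
  } else {
    if (length(severity_probs) != 5L) {
      stop("`severity_probs` must have 5 ordinal levels", call. = FALSE)
    }
    sev <- matrix(severity_probs, nrow = 40L, ncol = 5L, byrow = TRUE)
  }
  stopifnot_prob(sev, "severity_probs")
  if (any(abs(rowSums(sev) - 1) > 1e-8)) {
    stop("severity distributions must sum to 1 per item", call. = FALSE)
  }
  rownames(sev) <- names(stressor_prevalence)

  f <- resilience_factors()
  if (!is.matrix(factor_correlation) ||
      any(dim(factor_correlation) != c(9L, 9L)) ||
      max(abs(factor_correlation - t(factor_correlation))) > 1e-10) {
    stop("`factor_correlation` must be a symmetric 9 x 9 matrix",
         call. = FALSE)
  }
  ev <- eigen(factor_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`factor_correlation` is not positive-definite", call. = FALSE)
  }
  if (!all(f %in% names(factor_weights))) {
    stop("`factor_weights` must name all nine factors", call. = FALSE)
  }
  stopifnot_prob(missingness, "missingness")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  classes <- invalid_record_classes()
  bad <- setdiff(names(invalid_counts), classes)
  if (length(bad)) {
    stop(sprintf("unknown invalid-record class(es) %s; valid classes: %s",
                 paste(bad, collapse = ", "),
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  counts <- setNames(integer(length(classes)), classes)
  counts[names(invalid_counts)] <- as.integer(invalid_counts)
  if (any(counts < 0)) stop("`invalid_counts` must be nonnegative",
                            call. = FALSE)

  structure(
    list(
      n_participants = as.integer(n_participants),
      stressor_prevalence = stressor_prevalence,
      severity_probs = sev,
      factor_correlation = factor_correlation,
      factor_weights = factor_weights[f],
      mediation_paths = mediation_paths,
      exposure_slope = exposure_slope,
      baseline_symptoms = baseline_symptoms,
      noise_sd = noise_sd,
      exposure_propensity_sd = exposure_propensity_sd,
      covariate_distributions = covariate_distributions,
      missingness = missingness,
      invalid_counts = counts,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  stressor items:", length(x$stressor_prevalence),
      "(11 general + 29 specific)\n")
  cat("  missingness (trailing stressor block):", x$missingness, "\n")
  cat("  injected invalid records:", sum(x$invalid_counts), "\n")
  cat("  symptom model: P =", x$baseline_symptoms, "+",
      x$exposure_slope, "E - sum(w_k F_k) + N(0,", x$noise_sd, ")\n")
  invisible(x)
}
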