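# Synthetic survey-cohort generator with known ground truth.

#' Simulate a survey cohort with known ground truth
#'
#' Draws a cohort under the additive-linear symptom model described in
#' [cohort_config()]: standardized latent factor scores from a multivariate
#' normal (with positive appraisal style structurally determined by perceived
#' social support, and stress recovery by positive appraisal style, per the
#' configured mediation paths), Bernoulli stressor endorsements with ordinal
#' severities, a continuous GHQ-12 target discretized onto twelve 0-3 items
#' preserving the rounded total, independent socio-demographic covariates,
#' block missingness on the trailing stressor questions, and injected
#' defective records for every cleaning rule.
#'
#' Each sub-generator (covariates, factors, stressors, symptoms, missingness,
#' invalid records) draws from its own labelled seed stream, so enabling one
#' component never perturbs the draws of another. The result is bit-identical
#' for identical `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#'
#' @return A list of class `cohort` with elements
#'   \describe{
#'     \item{responses}{tibble of raw survey records, one row per respondent
#'       (age held as free text so that invalid entries are representable).}
#'     \item{truth}{ground truth: the parameters as used, per-participant
#'       latent factor scores, true exposure sums, the continuous symptom
#'       target, missingness flags and defect tags of injected records.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 200), seed = 1)
#' nrow(cohort$responses)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  n <- config$n_participants
  f <- resilience_factors()

  covars <- with_stream(seed, "covariates", draw_covariates(n, config))
  factors <- with_stream(seed, "factors", draw_factors(n, config))
  stress <- with_stream(seed, "stressors", draw_stressors(n, config))
  symp <- with_stream(seed, "symptoms",
                      draw_symptoms(n, config, factors, stress))
  miss <- with_stream(seed, "missingness",
                      runif(n) < config$missingness)

  responses <- tibble::tibble(
    id = sprintf("p%06d", seq_len(n)),
    age = as.character(covars$age),
    gender = covars$gender,
    country = covars$country,
    income = covars$income,
    income_scale = "final",
    education_years = covars$education_years,
    diagnosis = covars$diagnosis,
    free_text = NA_character_
  )
  responses <- tibble::as_tibble(cbind(responses, factors$scores,
                                       symp$items, stress$columns))

  # trailing stressor block left unanswered
  stressor_cols <- colnames(stress$columns)
  if (any(miss)) {
    responses[miss, stressor_cols] <- NA
  }

  truth <- list(
    factor_weights = config$factor_weights,
    mediation_paths = config$mediation_paths,
    exposure_slope = config$exposure_slope,
    baseline_symptoms = config$baseline_symptoms,
    noise_sd = config$noise_sd,
    factor_scores = factors$scores,
    e_g_true = stress$e_g_true,
    e_s_true = stress$e_s_true,
    e_true = symp$e_true,
    p_continuous = symp$p_cont,
    missing_block = responses$id[miss],
    invalid = tibble::tibble(id = character(), class = character())
  )

  out <- list(responses = responses, truth = truth)
  class(out) <- "cohort"

  if (sum(config$invalid_counts) > 0) {
    out <- inject_invalid_records(out, config$invalid_counts,
                                  seed = sub_seed(seed, "invalid"))
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$responses), "records,",
      nrow(x$truth$invalid), "tagged defective\n")
  invisible(x)
}

draw_covariates <- function(n, config) {
  d <- config$covariate_distributions
  sample_binned <- function(n, spec) {
    bin <- sample.int(length(spec$probs), n, replace = TRUE, prob = spec$probs)
    lo <- vapply(spec$breaks, `[`, numeric(1), 1)
    hi <- vapply(spec$breaks, `[`, numeric(1), 2)
    lo[bin] + floor(runif(n) * (hi[bin] - lo[bin] + 1))
  }
  list(
    age = sample_binned(n, d$age),
    gender = sample_cat(n, d$gender),
    country = sample_cat(n, d$country),
    income = sample_cat(n, d$income),
    education_years = sample_binned(n, d$education),
    diagnosis = sample_cat(n, d$diagnosis)
  )
}

draw_factors <- function(n, config) {
  f <- resilience_factors()
  r <- config$factor_correlation
  z <- matrix(rnorm(n * 9L), n, 9L) %*% chol(r)
  colnames(z) <- f
  a1 <- unname(config$mediation_paths[["pss_pas"]])
  a2 <- unname(config$mediation_paths[["pas_rec"]])
  # structural overwrite: the factor's own draw serves as its disturbance
  z[, "pas"] <- a1 * z[, "pss"] + sqrt(max(0, 1 - a1^2)) * z[, "pas"]
  z[, "rec"] <- a2 * z[, "pas"] + sqrt(max(0, 1 - a2^2)) * z[, "rec"]
  list(scores = as.data.frame(z))
}

# Logit intercept such that, after integrating out a N(0, sigma) shared
# propensity, the marginal endorsement probability equals `p` (Gauss-Hermite
# quadrature + root finding). Keeps configured prevalences calibrated.
calibrate_logit_intercept <- function(p, sigma) {
  if (sigma == 0) {
    return(qlogis(p))
  }
  gh <- pracma::gaussHermite(40)
  nodes <- sqrt(2) * sigma * gh$x
  weights <- gh$w / sqrt(pi)
  vapply(p, function(pj) {
    stats::uniroot(
      function(a) sum(weights * plogis(a + nodes)) - pj,
      lower = qlogis(pj) - 4 * sigma - 1, upper = qlogis(pj) + 4 * sigma + 1,
      tol = 1e-10
    )$root
  }, numeric(1))
}

draw_stressors <- function(n, config) {
  prev <- config$stressor_prevalence
  items <- names(prev)
  k <- length(items)
  u <- rnorm(n, sd = config$exposure_propensity_sd)
  # shared endorsement propensity on the logit scale, with item intercepts
  # calibrated so marginal endorsement matches the configured prevalence
  alpha <- calibrate_logit_intercept(prev, config$exposure_propensity_sd)
  p <- plogis(outer(u, alpha, `+`))
  endorsed <- matrix(as.integer(runif(n * k) < p), n, k)
  colnames(endorsed) <- items

  sev <- matrix(NA_integer_, n, k,
                dimnames = list(NULL, paste0("sev_", items)))
  cum <- t(apply(config$severity_probs, 1, cumsum))
  draw <- runif(n * k)
  lvl <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    lvl[, j] <- 1L + findInterval(draw[((j - 1L) * n + 1L):(j * n)],
                                  cum[j, 1:4])
  }
  sev[endorsed == 1L] <- lvl[endorsed == 1L]

  is_general <- startsWith(items, "gs_")
  sev0 <- sev
  sev0[is.na(sev0)] <- 0L
  e_g_true <- rowSums(sev0[, is_general, drop = FALSE])
  e_s_true <- rowSums(sev0[, !is_general, drop = FALSE])

  cols <- matrix(NA_integer_, n, 2L * k)
  colnames(cols) <- as.vector(rbind(items, paste0("sev_", items)))
  cols[, items] <- endorsed
  cols[, paste0("sev_", items)] <- sev
  list(
    columns = as.data.frame(cols),
    e_g_true = e_g_true,
    e_s_true = e_s_true
  )
}

draw_symptoms <- function(n, config, factors, stress) {
  zscore0 <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  zg <- zscore0(stress$e_g_true)
  zs <- zscore0(stress$e_s_true)
  e_true <- (zg + zs) / 2
  fw <- config$factor_weights
  fx <- as.matrix(factors$scores)[, names(fw), drop = FALSE] %*% fw
  p_cont <- config$baseline_symptoms + config$exposure_slope * e_true -
    as.numeric(fx) + rnorm(n, sd = config$noise_sd)
  p_cont <- pmin(pmax(p_cont, 0), 36)
  items <- discretize_ghq(p_cont)
  list(items = items, p_cont = p_cont, e_true = e_true)
}

# Distribute a continuous 0-36 target over twelve 0-3 items so the item total
# equals the rounded target (largest-remainder allocation of equal shares).
discretize_ghq <- function(p_cont) {
  total <- as.integer(round(p_cont))
  q <- total %/% 12L
  r <- total %% 12L
  items <- matrix(rep(q, each = 12L), nrow = length(total), ncol = 12L,
                  byrow = TRUE)
  bump <- outer(r, seq_len(12L), `>=`)
  items <- items + bump
  colnames(items) <- sprintf("ghq_%02d", 1:12)
  as.data.frame(items)
}

#' Append tagged defective records to a cohort
#'
#' Appends, per defect class, the requested number of records that each
#' violate exactly one cleaning rule: non-parseable or out-of-range age,
#' underage respondents, missing initial socio-demographics, household income
#' reported on the prefinal scale, and missing follow-up socio-demographics.
#' Every injected record is tagged in the ground truth so that cleaning can
#' be verified defect by defect.
#'
#' @param cohort A `cohort` (from [simulate_cohort()]).
#' @param invalid_counts Named nonnegative counts per defect class; valid
#'   names are given by [invalid_record_classes()].
#' @param seed RNG seed for the corrupted values.
#'
#' @return The cohort with appended records and updated `truth$invalid`.
#' @export
inject_invalid_records <- function(cohort, invalid_counts, seed = 1L) {
  classes <- invalid_record_classes()
  bad <- setdiff(names(invalid_counts), classes)
  if (length(bad)) {
    stop(sprintf("unknown invalid-record class(es) %s; valid classes: %s",
                 paste(bad, collapse = ", "),
                 paste(classes, collapse = ", ")), call. = FALSE)
  }
  counts <- setNames(integer(length(classes)), classes)
  counts[names(invalid_counts)] <- as.integer(invalid_counts)
  if (any(counts < 0)) {
    stop("`invalid_counts` must be nonnegative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0L) {
    return(cohort)
  }

  responses <- cohort$responses
  with_stream(seed, "inject", {
    template_rows <- sample.int(nrow(responses), total, replace = TRUE)
    injected <- responses[template_rows, ]
    injected$id <- sprintf("inv%05d", seq_len(total))
    cls <- rep(classes, counts)
    injected <- corrupt_records(injected, cls)
    cohort$responses <- tibble::as_tibble(rbind(responses, injected))
    cohort$truth$invalid <- tibble::as_tibble(rbind(
      cohort$truth$invalid,
      tibble::tibble(id = injected$id, class = cls)
    ))
  })
  cohort
}

# Vectorized corruption, one defect per record.
corrupt_records <- function(recs, cls) {
  i <- cls == "invalid_age"
  if (any(i)) {
    recs$age[i] <- sample(c("abc", "??", "none of your business",
                            "-4", "151"), sum(i), replace = TRUE)
  }
  i <- cls == "underage"
  if (any(i)) {
    recs$age[i] <- as.character(sample(8:17, sum(i), replace = TRUE))
  }
  i <- cls == "missing_initial_sociodemo"
  if (any(i)) {
    recs$age[i] <- NA_character_
    recs$gender[i] <- NA_character_
    recs$country[i] <- NA_character_
  }
  i <- cls == "prefinal_income"
  if (any(i)) {
    recs$income_scale[i] <- "prefinal"
  }
  i <- cls == "missing_followup_sociodemo"
  if (any(i)) {
    recs$education_years[i] <- NA_real_
    recs$income[i] <- NA_character_
  }
  recs
}
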