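# Covariate screening and the directed factor hypothesis tests.

build_formula <- function(outcome, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  as.formula(paste(outcome, "~", rhs))
}

# Treatment coding with the most frequent level as reference.
prep_categoricals <- function(d, cols) {
  for (col in intersect(cols, names(d))) {
    x <- d[[col]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      d[[col]] <- factor(x, levels = names(tab))
    }
  }
  d
}

#' Screen covariates by univariate likelihood-ratio tests
#'
#' For each covariate, fits the null model `outcome ~ 1` and the univariate
#' model `outcome ~ covariate` on the same complete rows, and compares twice
#' the log-likelihood difference to a chi-squared distribution with degrees
#' of freedom equal to the number of added model terms (categorical
#' covariates expand to indicator terms). A covariate is retained iff
#' `p < threshold`. A covariate with a single observed level contributes no
#' terms and is flagged unscreenable (never retained).
#'
#' @param data Data frame holding the outcome and covariates.
#' @param outcome Name of the outcome column (a resilience score).
#' @param covariates Character vector of covariate column names.
#' @param threshold Retention threshold on the LR p-value (default 0.2).
#' @return A tibble with `covariate`, `lr_stat`, `df`, `p`, `retained`.
#' @export
screen_covariates <- function(data, outcome, covariates, threshold = 0.2) {
  rows <- lapply(covariates, function(cov) {
    d <- data[complete.cases(data[, c(outcome, cov)]), c(outcome, cov)]
    x <- d[[cov]]
    n_levels <- if (is.numeric(x)) Inf else length(unique(x))
    if (nrow(d) < 3 || n_levels < 2 ||
        (is.numeric(x) && sd(x) == 0)) {
      return(tibble::tibble(covariate = cov, lr_stat = NA_real_, df = 0L,
                            p = NA_real_, retained = FALSE))
    }
    fit0 <- lm(build_formula(outcome, character(0)), data = d)
    fit1 <- lm(build_formula(outcome, cov), data = d)
    ll0 <- logLik(fit0)
    ll1 <- logLik(fit1)
    df <- attr(ll1, "df") - attr(ll0, "df")
    lr <- as.numeric(2 * (ll1 - ll0))
    p <- pchisq(lr, df = df, lower.tail = FALSE)
    tibble::tibble(covariate = cov, lr_stat = lr, df = as.integer(df),
                   p = p, retained = p < threshold)
  })
  do.call(rbind, rows)
}

#' Test a directed resilience-factor hypothesis
#'
#' Fits `outcome ~ covariates + factor` by least squares on complete rows
#' and reports the factor's coefficient with a Wald confidence interval
#' (t quantile, default 99%), its two-tailed p-value, and the adjusted-R^2
#' increase over the covariates-only model fitted on the same rows.
#'
#' @param data Data frame with outcome, factor and covariates.
#' @param outcome Outcome column name.
#' @param factor_name Numeric factor column name.
#' @param covariates Character vector of (screened) covariate names.
#' @param level Confidence level (default 0.99).
#' @param standardize If `TRUE`, outcome and factor are z-scored before
#'   fitting so the coefficient is a standardized beta.
#' @return A list of class `factor_fit`: `beta`, `se`, `p`, `ci`,
#'   `delta_adj_r2`, `adj_r2_full`, `n`, `loglik` and the full coefficient
#'   table `terms`.
#' @export
test_factor <- function(data, outcome, factor_name, covariates = character(0),
                        level = 0.99, standardize = FALSE) {
  if (factor_name %in% covariates) {
    stop(sprintf("collinear terms: '%s' appears as both factor and covariate",
                 factor_name), call. = FALSE)
  }
  cols <- c(outcome, factor_name, covariates)
  d <- data[complete.cases(data[, cols]), cols]
  d <- prep_categoricals(d, covariates)
  if (standardize) {
    d[[outcome]] <- as.numeric(scale(d[[outcome]]))
    d[[factor_name]] <- as.numeric(scale(d[[factor_name]]))
  }
  fit_cov <- lm(build_formula(outcome, covariates), data = d)
  fit_full <- lm(build_formula(outcome, c(covariates, factor_name)), data = d)
  if (any(is.na(coef(fit_full)))) {
    bad <- names(coef(fit_full))[is.na(coef(fit_full))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit_full)
  est <- sm$coefficients[factor_name, ]
  tq <- qt((1 + level) / 2, df = fit_full$df.residual)
  structure(
    list(
      factor = factor_name,
      beta = unname(est["Estimate"]),
      se = unname(est["Std. Error"]),
      p = unname(est["Pr(>|t|)"]),
      level = level,
      ci = unname(est["Estimate"] + c(-1, 1) * tq * est["Std. Error"]),
      delta_adj_r2 = sm$adj.r.squared - summary(fit_cov)$adj.r.squared,
      adj_r2_full = sm$adj.r.squared,
      n = nrow(d),
      loglik = as.numeric(logLik(fit_full)),
      terms = tibble::tibble(
        term = rownames(sm$coefficients),
        beta = sm$coefficients[, "Estimate"],
        se = sm$coefficients[, "Std. Error"],
        p = sm$coefficients[, "Pr(>|t|)"]
      )
    ),
    class = "factor_fit"
  )
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf(
    "<factor_fit> %s: beta = %.4f (%d%% CI %.4f, %.4f), p = %.3g, dAdjR2 = %.4f, n = %d\n",
    x$factor, x$beta, round(100 * x$level), x$ci[1], x$ci[2], x$p,
    x$delta_adj_r2, x$n
  ))
  invisible(x)
}

#' Test all directed factor hypotheses
#'
#' Runs [test_factor()] separately for each factor (the study design: one
#' multiple regression per directed hypothesis) and collects the results in
#' a forest-plot-ready table.
#'
#' @inheritParams test_factor
#' @param factors Character vector of factor column names.
#' @return A tibble with one row per factor: `factor`, `beta`, `se`, `p`,
#'   `lower`, `upper`, `delta_adj_r2`, `n`.
#' @export
test_all_factors <- function(data, outcome, factors = resilience_factors(),
                             covariates = character(0), level = 0.99,
                             standardize = FALSE) {
  rows <- lapply(factors, function(f) {
    fit <- test_factor(data, outcome, f, covariates, level, standardize)
    tibble::tibble(factor = f, beta = fit$beta, se = fit$se, p = fit$p,
                   lower = fit$ci[1], upper = fit$ci[2],
                   delta_adj_r2 = fit$delta_adj_r2, n = fit$n)
  })
  do.call(rbind, rows)
}

#' Bonferroni-corrected comparison threshold
#'
#' @param alpha Family-wise two-tailed alpha level, in (0, 1).
#' @param m Number of comparisons (`m >= 1`).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.01, 9) # 0.0011 at two significant figures
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot_scalar_number(alpha, "alpha")
  stopifnot_scalar_number(m, "m")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  alpha / m
}
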