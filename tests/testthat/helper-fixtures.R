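# Shared fixtures and independent oracles, built in code at test time.

# Small, fast generator configuration; override any knob.
tiny_config <- function(n = 200, ...) {
  args <- list(...)
  defaults <- list(n_participants = n, missingness = 0)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Generate, clean, score and compute resilience in one go; returns the
# analysed (complete) rows.
pipeline_scores <- function(config, seed = 1) {
  cohort <- simulate_cohort(config, seed = seed)
  cleaned <- clean_responses(cohort$responses)
  scored <- compute_resilience(score_participants(cleaned$participants))
  scored[!is.na(scored$res_c), ]
}

# Closed-form OLS oracle via the normal equations, with classical
# covariance: coefficients and standard errors.
ols_oracle <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = as.numeric(beta), se = unname(sqrt(diag(xtx_inv) * sigma2)))
}

# Explicit Gaussian log-likelihood of an lm-style fit (ML variance).
gaussian_loglik <- function(resid) {
  n <- length(resid)
  s2 <- sum(resid^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

# Nonparametric bootstrap percentile CI for the indirect effect a*b.
boot_indirect_ci <- function(d, x, m, y, covariates = character(0),
                             n_boot = 1000, level = 0.99) {
  xm_cols <- as.matrix(d[, c(x, covariates)])
  ab <- replicate(n_boot, {
    idx <- sample.int(nrow(d), replace = TRUE)
    X1 <- cbind(1, xm_cols[idx, , drop = FALSE])
    a <- qr.coef(qr(X1), d[[m]][idx])[2]
    X2 <- cbind(1, d[[m]][idx], xm_cols[idx, , drop = FALSE])
    b <- qr.coef(qr(X2), d[[y]][idx])[2]
    a * b
  })
  alpha <- 1 - level
  unname(stats::quantile(ab, c(alpha / 2, 1 - alpha / 2)))
}

# A minimal raw-response tibble of n clean, complete records, suitable for
# exercising the cleaning rules directly.
blank_responses <- function(n = 10) {
  cohort <- simulate_cohort(tiny_config(max(n, 10)), seed = 42)
  cohort$responses[seq_len(n), ]
}
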