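# Baron-Kenny mediation with asymptotic-normal (Sobel) indirect-effect CIs.

#' Asymptotic-normal (Sobel) confidence interval for an indirect effect
#'
#' First-order delta-method standard error of the product of two path
#' coefficients: `se = sqrt(a^2 se_b^2 + b^2 se_a^2)`, with the optional
#' second-order term `+ se_a^2 se_b^2` under the square root. The interval
#' is `a*b +/- z_{(1+level)/2} * se`.
#'
#' @param a,b Path coefficients (X to mediator; mediator to outcome).
#' @param se_a,se_b Their nonnegative standard errors.
#' @param level Confidence level in (0, 1), default 0.99.
#' @param second_order Include the second-order variance term.
#' @return A list: `indirect`, `se`, `lower`, `upper`.
#' @examples
#' sobel_ci(0.4, 0.1, 0.5, 0.1) # se = sqrt(0.0041) = 0.06403
#' @export
sobel_ci <- function(a, se_a, b, se_b, level = 0.99, second_order = FALSE) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)",
                                     call. = FALSE)
  if (se_a < 0 || se_b < 0) stop("standard errors must be nonnegative",
                                 call. = FALSE)
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (second_order) v <- v + se_a^2 * se_b^2
  se <- sqrt(v)
  z <- qnorm((1 + level) / 2)
  indirect <- a * b
  list(indirect = indirect, se = se,
       lower = indirect - z * se, upper = indirect + z * se)
}

#' Baron-Kenny mediation analysis
#'
#' Three least-squares fits on the same complete rows, all adjusted for the
#' screened covariates:
#' `Y ~ X + cov` (total effect `c`), `M ~ X + cov` (path `a`), and
#' `Y ~ X + M + cov` (paths `b` and direct effect `c'`). The indirect effect
#' is `a * b` with its asymptotic-normal CI from [sobel_ci()]. For these
#' nested linear fits `c = c' + a*b` holds as an algebraic identity.
#' "Partial mediation" is reported descriptively when both the indirect
#' effect's CI excludes zero and the direct path remains significant.
#'
#' @param data Data frame.
#' @param x,m,y Column names of predictor, mediator and outcome.
#' @param covariates Covariate column names adjusted for in all three fits.
#' @param level Confidence level (default 0.99).
#' @param second_order Passed to [sobel_ci()].
#' @return A list of class `mediation_result` with paths `a`, `b`, `c`,
#'   `c_prime` (each with `se` and `p`), `indirect`, `se_indirect`, `ci`,
#'   `partial_mediation`, `level`, `n`.
#' @export
baron_kenny <- function(data, x, m, y, covariates = character(0),
                        level = 0.99, second_order = FALSE) {
  cols <- c(x, m, y, covariates)
  d <- data[complete.cases(data[, cols]), cols]
  d <- prep_categoricals(d, covariates)
  if (isTRUE(all.equal(d[[x]], d[[m]]))) {
    stop("mediator is identical to the predictor (collinear)",
         call. = FALSE)
  }

  path <- function(fit, term) {
    est <- summary(fit)$coefficients[term, ]
    list(beta = unname(est["Estimate"]), se = unname(est["Std. Error"]),
         p = unname(est["Pr(>|t|)"]))
  }
  fit_total <- lm(build_formula(y, c(x, covariates)), data = d)
  fit_m <- lm(build_formula(m, c(x, covariates)), data = d)
  fit_full <- lm(build_formula(y, c(x, m, covariates)), data = d)

  a <- path(fit_m, x)
  b <- path(fit_full, m)
  cc <- path(fit_total, x)
  cp <- path(fit_full, x)
  ci <- sobel_ci(a$beta, a$se, b$beta, b$se, level, second_order)
  alpha <- 1 - level

  structure(
    list(
      x = x, m = m, y = y,
      a = a, b = b, c = cc, c_prime = cp,
      indirect = ci$indirect, se_indirect = ci$se,
      ci = c(ci$lower, ci$upper), level = level,
      partial_mediation = (ci$lower > 0 || ci$upper < 0) && cp$p < alpha,
      n = nrow(d)
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d)\n",
              x$x, x$m, x$y, x$n))
  cat(sprintf("  a = %.4f (se %.4f), b = %.4f (se %.4f)\n",
              x$a$beta, x$a$se, x$b$beta, x$b$se))
  cat(sprintf("  c = %.4f, c' = %.4f\n", x$c$beta, x$c_prime$beta))
  cat(sprintf("  indirect a*b = %.4f (se %.4f), %d%% CI [%.4f, %.4f]\n",
              x$indirect, x$se_indirect, round(100 * x$level),
              x$ci[1], x$ci[2]))
  if (x$partial_mediation) cat("  partial mediation (c' remains significant)\n")
  invisible(x)
}
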