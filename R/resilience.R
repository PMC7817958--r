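# Normative exposure-symptom regression and inverse-residual resilience.

#' Fit the normative exposure-symptom regression
#'
#' Least-squares fit of the symptom total `P` on the exposure index `E`
#' (plus `E^2` when `form = "quadratic"`), with intercept. The fitted curve
#' is the sample's normative predicted reactivity of mental health to
#' stressor exposure.
#'
#' @param e Exposure values (nonconstant, `n >= 3`).
#' @param p Symptom totals.
#' @param form `"linear"` (default) or `"quadratic"`.
#' @return A `normative_model` with coefficients, `r_squared` and `n`.
#' @export
fit_normative_curve <- function(e, p, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  ok <- complete.cases(e, p)
  e <- e[ok]
  p <- p[ok]
  if (length(e) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(e) == 0) stop("degenerate design: exposure is constant",
                       call. = FALSE)
  fit <- if (form == "linear") {
    lm(p ~ e)
  } else {
    lm(p ~ e + I(e^2))
  }
  tss <- sum((p - mean(p))^2)
  structure(
    list(
      form = form,
      coefficients = unname(coef(fit)),
      r_squared = if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_,
      n = length(e)
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model>", x$form, "fit, n =", x$n,
      ", R^2 =", signif(x$r_squared, 3), "\n")
  cat("  coefficients:", signif(x$coefficients, 5), "\n")
  invisible(x)
}

#' @export
predict.normative_model <- function(object, e, ...) {
  b <- object$coefficients
  if (object$form == "linear") {
    b[1] + b[2] * e
  } else {
    b[1] + b[2] * e + b[3] * e^2
  }
}

#' Inverse-residual resilience scores
#'
#' Returns `predicted(E) - observed P`: a participant whose symptoms lie
#' below the normative curve (relative under-reactivity) receives a POSITIVE
#' resilience score; one above the curve a negative score. Every downstream
#' sign in the package follows this convention.
#'
#' @param model A fitted [fit_normative_curve()] model.
#' @param e Exposure values.
#' @param p Observed symptom totals.
#' @return Numeric inverse residuals.
#' @export
residual_resilience <- function(model, e, p) {
  predict(model, e) - p
}

#' Compute all three resilience scores
#'
#' Fits three separate normative models of the symptom total on the
#' combined (`e_c`), general (`e_g`) and crisis-specific (`e_s`) exposure
#' indices, over complete records, and appends the inverse residuals as
#' `res_c`, `res_g`, `res_s`. Because each model is an intercept-carrying
#' least-squares fit, each score has mean zero over the fitting sample and
#' (for the linear form) zero sample correlation with its exposure index,
#' so individual differences in stressor exposure are inherently corrected
#' for.
#'
#' @param scored Participant tibble from [score_participants()].
#' @param form Curve form, passed to [fit_normative_curve()].
#' @return The tibble with `res_c`, `res_g`, `res_s` appended (`NA` for
#'   records without scores), with the three models in attribute
#'   `"normative_models"`.
#' @export
compute_resilience <- function(scored, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  ok <- !is.na(scored$p) & !is.na(scored$e_c)
  models <- list(
    c = fit_normative_curve(scored$e_c[ok], scored$p[ok], form),
    g = fit_normative_curve(scored$e_g[ok], scored$p[ok], form),
    s = fit_normative_curve(scored$e_s[ok], scored$p[ok], form)
  )
  n <- nrow(scored)
  res_c <- res_g <- res_s <- rep(NA_real_, n)
  res_c[ok] <- residual_resilience(models$c, scored$e_c[ok], scored$p[ok])
  res_g[ok] <- residual_resilience(models$g, scored$e_g[ok], scored$p[ok])
  res_s[ok] <- residual_resilience(models$s, scored$e_s[ok], scored$p[ok])
  scored$res_c <- res_c
  scored$res_g <- res_g
  scored$res_s <- res_s
  attr(scored, "normative_models") <- models
  scored
}
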