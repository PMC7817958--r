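# L1-penalized factor ranking: path, cross-validated penalty (1-SE rule),
# deviance ratio, repeated-run selection stability. The path itself is
# solved by glmnet's coordinate descent; penalty selection, deviance ratio,
# stability repeats and ranking live here.

#' Log-spaced penalty grid
#'
#' 100 points from the smallest penalty giving the all-zero model
#' (`lambda_max = max_j |x_j' y| / n` on centered data) down by a factor
#' `1e-3`.
#'
#' @param x Numeric design matrix.
#' @param y Response.
#' @param n_lambda Grid size.
#' @param ratio Ratio of smallest to largest penalty.
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid <- function(x, y, n_lambda = 100, ratio = 1e-3) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(xc, yc))) / length(y)
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_lambda))
}

#' Fit an L1-penalized least-squares coefficient path
#'
#' Gaussian lasso (intercept unpenalized) over a descending penalty grid.
#'
#' @param x Numeric design matrix (rows = participants).
#' @param y Numeric response (the resilience score).
#' @param lambda Penalty grid; defaults to [lambda_grid()].
#' @param standardize Standardize columns internally (glmnet default
#'   behaviour); set `FALSE` when the design is already standardized.
#' @return A list of class `lasso_path`: `lambda`, `beta` (coefficients,
#'   terms x penalties), `intercept`, and the underlying `glmnet` fit.
#' @export
fit_lasso_path <- function(x, y, lambda = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 1 || nrow(x) == 0) stop("empty design", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_grid(x, y)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambda, standardize = standardize,
                        thresh = 1e-12)
  structure(
    list(lambda = lambda, beta = as.matrix(fit$beta),
         intercept = as.numeric(fit$a0), fit = fit),
    class = "lasso_path"
  )
}

#' Select the penalty by the one-standard-error rule
#'
#' The selected penalty is the LARGEST one whose cross-validation error does
#' not exceed the minimum cross-validation error plus one standard error (the
#' SE at the minimizing penalty) — the simplest model whose accuracy is
#' comparable to the best.
#'
#' @param cv_mean,cv_se Aligned CV error means and standard errors.
#' @param lambda Aligned penalty grid.
#' @return The selected penalty value.
#' @export
select_lambda_1se <- function(cv_mean, cv_se, lambda) {
  ok <- is.finite(cv_mean)
  if (!any(ok)) stop("all cross-validation errors are missing", call. = FALSE)
  i_min <- which(ok)[which.min(cv_mean[ok])]
  cutoff <- cv_mean[i_min] + cv_se[i_min]
  max(lambda[ok & cv_mean <= cutoff])
}

#' Cross-validate the lasso over a fixed penalty grid
#'
#' K-fold cross-validation with mean-squared-error loss: fold assignment is
#' an exact partition, each fold's model is fitted on the remaining folds
#' over the full grid, and the CV curve aggregates fold-level MSEs
#' (size-weighted mean; SE over fold means).
#'
#' @inheritParams fit_lasso_path
#' @param nfolds Number of folds (default 10).
#' @param foldid Optional explicit fold assignment (1..nfolds per row).
#' @return A list of class `cv_lasso`: `lambda`, `cv_mean`, `cv_se`,
#'   `lambda_min`, `lambda_opt` (1-SE rule), `foldid`.
#' @export
cv_lasso <- function(x, y, nfolds = 10, lambda = NULL, foldid = NULL,
                     standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < nfolds) stop("fewer rows than folds", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_grid(x, y)
  if (is.null(foldid)) {
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
  }
  fold_mse <- matrix(NA_real_, nfolds, length(lambda))
  fold_n <- integer(nfolds)
  for (k in seq_len(nfolds)) {
    test <- foldid == k
    fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                          family = "gaussian", alpha = 1, lambda = lambda,
                          standardize = standardize, thresh = 1e-10)
    pred <- predict(fit, newx = x[test, , drop = FALSE])
    err <- (pred - y[test])^2
    fold_mse[k, seq_len(ncol(pred))] <- colMeans(err)
    fold_n[k] <- sum(test)
  }
  cv_mean <- colSums(fold_mse * fold_n) / sum(fold_n)
  cv_se <- apply(fold_mse, 2, sd) / sqrt(nfolds)
  structure(
    list(
      lambda = lambda, cv_mean = cv_mean, cv_se = cv_se,
      lambda_min = lambda[which.min(cv_mean)],
      lambda_opt = select_lambda_1se(cv_mean, cv_se, lambda),
      foldid = foldid
    ),
    class = "cv_lasso"
  )
}

#' Proportion of deviance explained
#'
#' For a Gaussian fit, `1 - RSS / RSS_0` relative to the intercept-only
#' (null) model, clipped to `[0, 1]`.
#'
#' @param fitted Fitted values of the model.
#' @param y Observed response (nonconstant).
#' @return Deviance ratio in `[0, 1]`.
#' @export
deviance_ratio <- function(fitted, y) {
  if (sd(y) == 0) stop("zero-variance response", call. = FALSE)
  rss <- sum((y - fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  min(max(1 - rss / rss0, 0), 1)
}

#' Selection stability over repeated lasso runs
#'
#' Repeats the full cross-validation + 1-SE fit with re-randomized fold
#' assignments (optionally also resampling rows with replacement) and
#' reports, per term, the fraction of runs in which its coefficient at that
#' run's selected penalty is nonzero.
#'
#' @inheritParams cv_lasso
#' @param runs Number of repeated runs (`>= 1`).
#' @param seed Seed of the run streams (each run draws from its own labelled
#'   stream, so results are reproducible and order-independent).
#' @param resample_rows Bootstrap-resample rows in each run.
#' @return Named numeric vector of selection frequencies in `[0, 1]`.
#' @export
stability_selection <- function(x, y, runs = 800, seed = 1, nfolds = 10,
                                lambda = NULL, standardize = TRUE,
                                resample_rows = FALSE) {
  if (runs < 1) stop("`runs` must be at least 1", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(lambda)) lambda <- lambda_grid(x, y)
  selected <- matrix(FALSE, runs, ncol(x))
  for (r in seq_len(runs)) {
    with_stream(seed, paste0("stability_run_", r), {
      if (resample_rows) {
        idx <- sample.int(nrow(x), replace = TRUE)
      } else {
        idx <- seq_len(nrow(x))
      }
      xr <- x[idx, , drop = FALSE]
      yr <- y[idx]
      cv <- cv_lasso(xr, yr, nfolds = nfolds, lambda = lambda,
                     standardize = standardize)
      fit <- glmnet::glmnet(xr, yr, family = "gaussian", alpha = 1,
                            lambda = lambda, standardize = standardize,
                            thresh = 1e-10)
      beta <- as.matrix(fit$beta)[, which(lambda == cv$lambda_opt)]
      selected[r, ] <- beta != 0
    })
  }
  setNames(colMeans(selected), colnames(x))
}

#' Rank factors by coefficient magnitude
#'
#' Rank 1 is the largest `|beta|`; ties are broken by the order of the input
#' vector (the canonical factor order). An all-zero coefficient vector is
#' flagged degenerate with a warning.
#'
#' @param coefs Named numeric vector of coefficients at the selected
#'   penalty.
#' @return Named integer ranks (a permutation of `1..length(coefs)`).
#' @export
rank_factors <- function(coefs) {
  if (all(coefs == 0)) {
    warning("all coefficients are zero; ranks are the tie-rule order",
            call. = FALSE)
  }
  ord <- order(-abs(coefs), seq_along(coefs))
  ranks <- integer(length(coefs))
  ranks[ord] <- seq_along(coefs)
  setNames(ranks, names(coefs))
}

#' Combined penalized ranking of resilience factors
#'
#' Builds a standardized design from the factors and (dummy-coded, screened)
#' covariates, fits the lasso path, selects the penalty by cross-validation
#' with the 1-SE rule, and reports coefficients at the selected penalty on
#' the standardized scale (so magnitudes are comparable across factors),
#' the deviance ratio, repeated-run selection frequencies, and the factor
#' ranks by coefficient magnitude.
#'
#' @param data Data frame with outcome, factors and covariates.
#' @param outcome Outcome column (a resilience score).
#' @param factors Factor column names (ranked terms).
#' @param covariates Covariate column names (enter the design, unranked).
#' @param runs Stability-selection repeats (default 800, matching a
#'   full-scale stability audit; reduce for quick analyses).
#' @param nfolds CV folds (default 10).
#' @param seed RNG seed.
#' @param resample_rows Passed to [stability_selection()].
#' @return A list of class `lasso_result`: penalty grid, coefficient path,
#'   CV curve, `lambda_min`, `lambda_opt`, `coef_opt`, `deviance_ratio`,
#'   `selection_freq`, `ranks` (factors only), `n`.
#' @export
lasso_rank <- function(data, outcome, factors = resilience_factors(),
                       covariates = character(0), runs = 800, nfolds = 10,
                       seed = 1, resample_rows = FALSE) {
  cols <- c(outcome, factors, covariates)
  d <- data[complete.cases(data[, cols]), cols]
  d <- prep_categoricals(d, covariates)
  # a covariate constant within the analysed rows carries no information
  covariates <- covariates[vapply(covariates, function(cv) {
    length(unique(d[[cv]])) > 1
  }, logical(1))]
  y <- d[[outcome]]

  xf <- as.matrix(d[, factors])
  if (length(covariates) > 0) {
    mm <- model.matrix(build_formula(outcome, covariates), data = d)
    xc <- mm[, -1, drop = FALSE]
    x <- cbind(xf, xc)
  } else {
    x <- xf
  }
  x <- scale(x)
  constant <- attr(x, "scaled:scale") == 0
  if (any(constant)) x <- x[, !constant, drop = FALSE]
  lambda <- lambda_grid(x, y)

  path <- fit_lasso_path(x, y, lambda = lambda, standardize = FALSE)
  cv <- with_stream(seed, "cv", {
    cv_lasso(x, y, nfolds = nfolds, lambda = lambda, standardize = FALSE)
  })
  i_opt <- which(lambda == cv$lambda_opt)
  coef_opt <- path$beta[, i_opt]
  fitted_opt <- path$intercept[i_opt] + as.numeric(x %*% coef_opt)
  freq <- stability_selection(x, y, runs = runs, seed = seed,
                              nfolds = nfolds, lambda = lambda,
                              standardize = FALSE,
                              resample_rows = resample_rows)
  structure(
    list(
      lambda = lambda, beta = path$beta, intercept = path$intercept,
      cv_mean = cv$cv_mean, cv_se = cv$cv_se,
      lambda_min = cv$lambda_min, lambda_opt = cv$lambda_opt,
      coef_opt = coef_opt,
      deviance_ratio = deviance_ratio(fitted_opt, y),
      selection_freq = freq,
      ranks = rank_factors(coef_opt[intersect(factors, names(coef_opt))]),
      factors = factors,
      n = nrow(d)
    ),
    class = "lasso_result"
  )
}

#' @export
print.lasso_result <- function(x, ...) {
  cat("<lasso_result> n =", x$n, "\n")
  cat(sprintf("  lambda_min = %.5f, lambda_opt (1-SE) = %.5f\n",
              x$lambda_min, x$lambda_opt))
  cat(sprintf("  deviance ratio at lambda_opt = %.3f\n", x$deviance_ratio))
  cat("  factor ranks:\n")
  r <- sort(x$ranks)
  for (nm in names(r)) {
    cat(sprintf("    %d. %-4s beta = %+.4f  (selected in %.0f%% of runs)\n",
                r[[nm]], nm, x$coef_opt[[nm]],
                100 * x$selection_freq[[nm]]))
  }
  invisible(x)
}
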