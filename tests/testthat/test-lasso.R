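# An orthonormal-by-columns design with X'X = n I, so the lasso solution is
# the soft-thresholded OLS estimate coordinate by coordinate.
orthonormal_design <- function(n, p) {
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  q <- q - matrix(colMeans(q), n, p, byrow = TRUE)
  q <- qr.Q(qr(q)) # re-orthogonalize after centering
  x <- q * sqrt(n)
  colnames(x) <- paste0("x", seq_len(p))
  x
}

test_that("a large enough penalty shrinks every coefficient to zero", {
  set.seed(61)
  x <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  path <- fit_lasso_path(x, y, standardize = FALSE)
  expect_true(all(path$beta[, 1] == 0)) # at lambda_max the model is null
  huge <- fit_lasso_path(x, y, lambda = c(1e4, 1e3))
  expect_true(all(huge$beta == 0))
})

test_that("an unpenalized fit equals the OLS oracle", {
  set.seed(62)
  x <- matrix(rnorm(300), 100, 3)
  y <- 1 + x %*% c(0.5, -0.3, 0.2) + rnorm(100, sd = 0.5)
  grid <- c(lambda_grid(x, y), 0)
  path <- fit_lasso_path(x, y, lambda = grid, standardize = FALSE)
  oracle <- ols_oracle(x, y)
  expect_equal(unname(path$beta[, length(grid)]), oracle$beta[-1],
               tolerance = 1e-6)
})

test_that("orthonormal designs give the closed-form soft-threshold solution", {
  set.seed(63)
  n <- 400
  x <- orthonormal_design(n, 5)
  y <- x %*% c(1, -0.6, 0.3, 0.1, 0) + rnorm(n, sd = 0.4)
  beta_ols <- as.numeric(crossprod(x, y - mean(y)) / n)
  for (lam in c(0.05, 0.2, 0.5)) {
    path <- fit_lasso_path(x, y, lambda = c(1, lam), standardize = FALSE)
    soft <- sign(beta_ols) * pmax(abs(beta_ols) - lam, 0)
    expect_equal(unname(path$beta[, 2]), soft, tolerance = 1e-8)
  }
})

test_that("the predictor most correlated with the response enters first", {
  set.seed(64)
  x <- orthonormal_design(300, 4)
  y <- x %*% c(0.2, 1.5, -0.4, 0.05) + rnorm(300, sd = 0.3)
  path <- fit_lasso_path(x, y, standardize = FALSE)
  first_nonzero <- apply(path$beta != 0, 1, function(r) {
    if (any(r)) which(r)[1] else Inf
  })
  expect_equal(unname(which.min(first_nonzero)), 2L)
})

test_that("the 1-SE rule picks the largest penalty within one SE of the minimum", {
  lam <- c(4, 3, 2, 1)
  expect_equal(select_lambda_1se(c(10, 5, 4, 6), rep(1, 4), lam), 3)
  # monotone decreasing CV error with tiny SEs collapses onto lambda_min
  expect_equal(select_lambda_1se(c(4, 3, 2, 1), rep(1e-9, 4), lam), 1)
  expect_error(select_lambda_1se(rep(NaN, 4), rep(1, 4), lam), "missing")
})

test_that("the 1-SE rule agrees with an exhaustive scan oracle", {
  set.seed(65)
  for (i in 1:50) {
    k <- sample(5:30, 1)
    lam <- sort(runif(k, 0.01, 5), decreasing = TRUE)
    means <- runif(k, 1, 10)
    ses <- runif(k, 0.1, 2)
    chosen <- select_lambda_1se(means, ses, lam)
    cutoff <- min(means) + ses[which.min(means)]
    admissible <- lam[means <= cutoff]
    expect_equal(chosen, max(admissible))
  }
})

test_that("the deviance ratio is 1 - RSS ratio, clipped to [0, 1]", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(deviance_ratio(y, y), 1)
  expect_equal(deviance_ratio(rep(mean(y), 5), y), 0)
  fitted <- c(1.5, 2.5, 2.5, 4.5, 4)
  rss <- sum((y - fitted)^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(deviance_ratio(fitted, y), 1 - rss / rss0)
  expect_equal(deviance_ratio(y + 100, y), 0) # worse than null clips at 0
  expect_error(deviance_ratio(rep(1, 5), rep(2, 5)), "zero-variance")
})

test_that("cross-validation folds exactly partition the rows", {
  set.seed(66)
  x <- matrix(rnorm(500), 100, 5)
  y <- rnorm(100)
  cv <- cv_lasso(x, y, nfolds = 10)
  expect_equal(sort(unique(cv$foldid)), 1:10)
  expect_equal(length(cv$foldid), 100)
  expect_equal(as.vector(table(cv$foldid)), rep(10L, 10))
  expect_gte(cv$lambda_opt, cv$lambda_min)
})

test_that("a single stability run yields zero-one frequencies", {
  set.seed(67)
  x <- matrix(rnorm(600), 100, 6)
  y <- x[, 1] + rnorm(100)
  freq <- stability_selection(x, y, runs = 1, seed = 1)
  expect_true(all(freq %in% c(0, 1)))
})

test_that("pure-noise predictors are rarely selected, strong ones always", {
  set.seed(68)
  n <- 600
  x <- cbind(signal = rnorm(n), noise = rnorm(n), noise2 = rnorm(n))
  y <- 1.5 * x[, "signal"] + rnorm(n)
  freq <- stability_selection(x, y, runs = 20, seed = 5)
  expect_equal(unname(freq[["signal"]]), 1)
  expect_lt(freq[["noise"]], 1)
})

test_that("stability selection is reproducible from its seed", {
  set.seed(69)
  x <- matrix(rnorm(400), 100, 4)
  y <- x[, 1] + rnorm(100)
  f1 <- stability_selection(x, y, runs = 5, seed = 3)
  f2 <- stability_selection(x, y, runs = 5, seed = 3)
  expect_identical(f1, f2)
})

test_that("factors are ranked by coefficient magnitude with a stable tie rule", {
  expect_equal(rank_factors(c(a = 0.3, b = -0.4, c = 0.1)),
               c(a = 2L, b = 1L, c = 3L))
  expect_warning(r0 <- rank_factors(c(a = 0, b = 0)), "degenerate|tie-rule")
  expect_equal(r0, c(a = 1L, b = 2L))
  # ties broken by input (canonical) order
  expect_equal(rank_factors(c(a = 0.5, b = -0.5, c = 1)),
               c(a = 2L, b = 3L, c = 1L))
})

test_that("whole-pipeline ranks recover the generator's weight ordering", {
  # independent factors so partial effects coincide with the weights
  cfg <- tiny_config(10000, factor_correlation = diag(9),
                     mediation_paths = c(pss_pas = 0, pas_rec = 0))
  w_abs <- abs(cfg$factor_weights)
  taus <- vapply(1:8, function(seed) {
    d <- pipeline_scores(cfg, seed = seed)
    fit <- lasso_rank(d, "res_c", runs = 1, seed = seed)
    # rank 1 = largest weight, so weights and ranks must be anti-concordant
    -cor(w_abs[names(fit$ranks)], fit$ranks, method = "kendall")
  }, numeric(1))
  expect_gte(mean(taus), 0.8)
})

test_that("a dominant generated weight ordering is reproduced in the ranks", {
  w <- setNames(rep(0.1, 9), resilience_factors())
  w["rec"] <- 1.2
  w["pac"] <- 0.8
  hits <- vapply(1:5, function(seed) {
    d <- pipeline_scores(
      tiny_config(8000, factor_weights = w, factor_correlation = diag(9)),
      seed = seed
    )
    fit <- lasso_rank(d, "res_c", runs = 1, seed = seed)
    fit$ranks[["rec"]] == 1 && fit$ranks[["pac"]] == 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("empty designs are rejected", {
  expect_error(fit_lasso_path(matrix(numeric(0), 0, 0), numeric(0)), "empty")
})
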