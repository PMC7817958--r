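test_that("likelihood-ratio screening matches an explicit two-model oracle", {
  d <- data.frame(
    res = c(1.2, 0.5, -0.3, 2.1, 1.8, -0.9, 0.2, 1.1, -1.4, 0.7),
    x = c(0.3, 0.1, -0.2, 1.0, 0.9, -0.5, 0.0, 0.6, -0.8, 0.2)
  )
  out <- screen_covariates(d, "res", "x")
  r0 <- d$res - mean(d$res)
  fit <- ols_oracle(d$x, d$res)
  r1 <- d$res - (fit$beta[1] + fit$beta[2] * d$x)
  lr_oracle <- 2 * (gaussian_loglik(r1) - gaussian_loglik(r0))
  expect_equal(out$lr_stat, lr_oracle, tolerance = 1e-8)
  expect_equal(out$df, 1L)
})

test_that("a perfect covariate is retained and a constant one is unscreenable", {
  set.seed(41)
  d <- data.frame(res = rnorm(100))
  d$copy <- d$res
  d$flat <- "only_level"
  out <- screen_covariates(d, "res", c("copy", "flat"))
  expect_true(out$retained[out$covariate == "copy"])
  expect_lt(out$p[out$covariate == "copy"], 1e-12)
  expect_false(out$retained[out$covariate == "flat"])
  expect_equal(out$df[out$covariate == "flat"], 0L)
})

test_that("categorical covariates expand to indicator-term degrees of freedom", {
  set.seed(42)
  d <- data.frame(res = rnorm(200),
                  grp = sample(c("a", "b", "c", "d"), 200, replace = TRUE))
  out <- screen_covariates(d, "res", "grp")
  expect_equal(out$df, 3L)
})

test_that("null covariates are retained at about the threshold rate", {
  set.seed(43)
  retained <- vapply(1:200, function(i) {
    d <- data.frame(res = rnorm(2000), x = rnorm(2000))
    screen_covariates(d, "res", "x")$retained
  }, logical(1))
  # binomial check around 0.2
  expect_lt(abs(mean(retained) - 0.2), 3 * sqrt(0.2 * 0.8 / 200))
})

test_that("factor fits match the normal-equations + classical-covariance oracle", {
  set.seed(44)
  for (i in 1:5) {
    n <- 60
    d <- data.frame(res = rnorm(n), f = rnorm(n), c1 = rnorm(n),
                    c2 = rnorm(n))
    d$res <- d$res + 0.5 * d$f + 0.2 * d$c1
    fit <- test_factor(d, "res", "f", covariates = c("c1", "c2"))
    oracle <- ols_oracle(cbind(d$c1, d$c2, d$f), d$res)
    expect_equal(fit$beta, oracle$beta[4], tolerance = 1e-8)
    expect_equal(fit$se, oracle$se[4], tolerance = 1e-8)
  }
})

test_that("collinear designs are rejected with the offending term named", {
  set.seed(45)
  d <- data.frame(res = rnorm(50), f = rnorm(50))
  d$dup <- d$f
  expect_error(test_factor(d, "res", "f", covariates = "f"), "collinear")
  expect_error(test_factor(d, "res", "f", covariates = "dup"), "collinear")
})

test_that("an orthogonal factor shows no effect and no added variance", {
  set.seed(46)
  d <- data.frame(res = rnorm(20000), f = rnorm(20000))
  fit <- test_factor(d, "res", "f")
  expect_true(fit$ci[1] < 0 && fit$ci[2] > 0)
  expect_lt(abs(fit$delta_adj_r2), 0.002)
})

test_that("a generated factor weight is recovered within three standard errors", {
  w <- setNames(rep(0, 9), resilience_factors())
  w["pas"] <- 0.3
  cfg <- tiny_config(5000, factor_weights = w,
                     factor_correlation = diag(9))
  d <- pipeline_scores(cfg, seed = 1)
  fit <- test_factor(d, "res_c", "pas")
  expect_lt(abs(fit$beta - 0.3), 3 * fit$se)
})

test_that("Wald intervals achieve nominal 99% coverage", {
  set.seed(47)
  covered <- vapply(1:1000, function(i) {
    n <- 1000
    x <- rnorm(n)
    z <- rnorm(n)
    y <- 0.3 * x + 0.2 * z + rnorm(n)
    fit <- test_factor(data.frame(res = y, f = x, z = z), "res", "f",
                       covariates = "z", level = 0.99)
    fit$ci[1] <= 0.3 && 0.3 <= fit$ci[2]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.99), 0.02)
})

test_that("hypothesized signs are estimated faithfully at scale", {
  for (seed in 1:5) {
    d <- pipeline_scores(tiny_config(5000), seed = seed)
    fits <- test_all_factors(d, "res_c")
    signs <- sign(fits$beta)
    expected <- ifelse(fits$factor == "neu", -1, 1)
    expect_equal(signs, expected)
  }
})

test_that("the Bonferroni comparison threshold is alpha over m", {
  expect_equal(signif(bonferroni_threshold(0.01, 9), 2), 0.0011)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 2), 0.005)
  expect_error(bonferroni_threshold(0.01, 0), "at least 1")
  expect_error(bonferroni_threshold(1.2, 9), "in \\(0, 1\\)")
})
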