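test_that("default configuration encodes the documented prevalences", {
  cfg <- cohort_config()
  prev <- cfg$stressor_prevalence
  expect_length(prev, 40)
  expect_equal(sum(startsWith(names(prev), "gs_")), 11)
  expect_equal(sum(startsWith(names(prev), "cs_")), 29)
  expect_equal(prev[["cs_media_coverage"]], 0.93)
  expect_equal(sort(prev[startsWith(names(prev), "cs_")],
                    decreasing = TRUE)[1:4],
               c(cs_media_coverage = 0.93, cs_leisure_restricted = 0.90,
                 cs_loss_social_contact = 0.88,
                 cs_restricted_leave_home = 0.86))
  expect_equal(prev[["gs_negative_political_events"]], 0.83)
  expect_equal(prev[["gs_family_conflicts"]], 0.62)
  expect_equal(prev[["gs_work_stress"]], 0.61)
  # defaults are deterministic
  expect_identical(cohort_config(), cohort_config())
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(cohort_config(n_participants = 0), "positive integer")
  bad_corr <- diag(9)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 1.5 # breaks positive-definiteness
  expect_error(cohort_config(factor_correlation = bad_corr),
               "positive-definite")
  expect_error(cohort_config(invalid_counts = c(bogus_rule = 3)),
               "valid classes")
  expect_error(cohort_config(severity_probs = rep(0.5, 5)), "sum to 1")
})

test_that("identical (config, seed) reproduces the cohort bit for bit", {
  cfg <- tiny_config(300, missingness = 0.2,
                     invalid_counts = c(underage = 4, prefinal_income = 2))
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth$invalid, b$truth$invalid)
  c <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$responses, c$responses))
})

test_that("noise-free, factor-free cohorts have symptoms affine in exposure", {
  w0 <- setNames(rep(0, 9), resilience_factors())
  cfg <- tiny_config(400, noise_sd = 0, factor_weights = w0,
                     exposure_slope = 5)
  cohort <- simulate_cohort(cfg, seed = 2)
  p <- score_ghq12(cohort$responses[, sprintf("ghq_%02d", 1:12)])
  # affine up to the 1-point discretization of the item total
  expect_gt(cor(p, cohort$truth$e_true), 0.99)
  expect_lt(max(abs(p - cohort$truth$p_continuous)), 0.5 + 1e-9)
})

test_that("no missingness and no injected defects give an all-complete cohort", {
  cohort <- simulate_cohort(tiny_config(150), seed = 3)
  cleaned <- clean_responses(cohort$responses)
  expect_equal(cleaned$report$n_removed, 0)
  expect_equal(cleaned$report$n_complete, 150)
})

test_that("endorsement frequencies converge to the configured prevalences", {
  cfg <- cohort_config(n_participants = 20000)
  cohort <- simulate_cohort(cfg, seed = 11)
  prev <- cfg$stressor_prevalence
  observed <- vapply(names(prev), function(col) {
    mean(cohort$responses[[col]], na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(abs(observed - prev)), 0.02)
})

test_that("with all factor weights zero no factor correlates with resilience", {
  w0 <- setNames(rep(0, 9), resilience_factors())
  max_r <- vapply(1:20, function(seed) {
    d <- pipeline_scores(tiny_config(10000, factor_weights = w0), seed = seed)
    max(abs(vapply(resilience_factors(), function(f) {
      cor(d[[f]], d$res_c)
    }, numeric(1))))
  }, numeric(1))
  expect_lt(max(max_r), 0.05)
})

test_that("nonzero factor weights are recovered by the regression module", {
  # partial effects of the factors equal the generator weights
  cfg <- tiny_config(5000)
  w <- cfg$factor_weights
  d <- pipeline_scores(cfg, seed = 5)
  f <- resilience_factors()
  for (k in f) {
    fit <- test_factor(d, "res_c", k, covariates = setdiff(f, k))
    expect_lt(abs(fit$beta - w[[k]]), 3 * fit$se)
  }
})

test_that("injected defective records are constructed and tagged as requested", {
  cohort <- simulate_cohort(tiny_config(100), seed = 4)
  same <- inject_invalid_records(cohort, c(underage = 0), seed = 1)
  expect_identical(same$responses, cohort$responses)

  inj <- inject_invalid_records(cohort, c(underage = 5), seed = 1)
  expect_equal(nrow(inj$responses), 105)
  added <- inj$responses[101:105, ]
  ages <- as.numeric(added$age)
  expect_true(all(ages >= 0 & ages < 18))
  expect_equal(inj$truth$invalid$class, rep("underage", 5))

  expect_error(inject_invalid_records(cohort, c(nonsense = 1)),
               "valid classes")
})

test_that("injected defects round-trip through cleaning", {
  cohort <- simulate_cohort(tiny_config(100), seed = 9)
  inj <- inject_invalid_records(
    cohort, c(invalid_age = 3, prefinal_income = 2), seed = 2
  )
  cleaned <- clean_responses(inj$responses)
  expect_equal(cleaned$report$n_removed, 5)
  expect_equal(cleaned$report$n_valid, 100)
  removed_ids <- cleaned$report$dispositions$id[
    cleaned$report$dispositions$disposition %in% invalid_record_classes()
  ]
  expect_setequal(removed_ids, inj$truth$invalid$id)
})
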