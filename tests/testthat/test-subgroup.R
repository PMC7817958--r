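test_that("per-level slopes from the interaction model equal stratified fits", {
  set.seed(71)
  n <- 400
  d <- tibble::tibble(
    res_c = rnorm(n),
    pas = rnorm(n),
    gender = sample(c("female", "male"), n, replace = TRUE),
    age = sample(20:70, n, replace = TRUE)
  )
  d$res_c <- d$res_c + ifelse(d$gender == "male", 0.6, 0.2) * d$pas
  tab <- interaction_model(d, "res_c", "pas", "gender")
  for (lv in tab$level) {
    strat <- d[d$gender == lv, ]
    fit <- ols_oracle(strat$pas, strat$res_c)
    expect_equal(tab$beta[tab$level == lv], fit$beta[2], tolerance = 1e-8)
  }
  expect_lt(attr(tab, "interaction_p"), 0.05)
})

test_that("a level with an attenuated slope is estimated as attenuated", {
  set.seed(72)
  n <- 10000
  grp <- sample(c("18-30", "31-45", "46-60", "61+"), n, replace = TRUE)
  pac <- rnorm(n)
  slope <- ifelse(grp == "61+", 0.3, 0.6) # oldest level halved
  d <- tibble::tibble(
    res_c = slope * pac + rnorm(n),
    pac = pac,
    age = c("18-30" = 25, "31-45" = 40, "46-60" = 50, "61+" = 70)[grp]
  )
  tab <- interaction_model(d, "res_c", "pac", "age")
  old <- tab$beta[tab$level == "61+"]
  rest <- mean(tab$beta[tab$level != "61+"])
  expect_lt(abs(old - 0.3), 3 * tab$se[tab$level == "61+"])
  expect_lt(abs(old / rest - 0.5), 0.15)
  expect_lt(attr(tab, "interaction_p"), 0.01)
})

test_that("excluded categories drop out with the sample reduced", {
  d <- pipeline_scores(tiny_config(800), seed = 21)
  tab <- interaction_model(d, "res_c", "pas", "gender")
  expect_setequal(tab$level, c("female", "male"))
  expect_equal(sum(tab$n), sum(d$gender != "diverse"))
  expect_error(
    interaction_model(d[d$gender == "female", ], "res_c", "pas", "gender"),
    "single level"
  )
})

test_that("interaction LR test holds its nominal type-I error under the null", {
  set.seed(73)
  p_values <- vapply(1:500, function(i) {
    n <- 400
    d <- tibble::tibble(
      res_c = rnorm(n),
      pas = rnorm(n),
      gender = sample(c("female", "male"), n, replace = TRUE)
    )
    d$res_c <- d$res_c + 0.4 * d$pas # main effect, no interaction
    attr(interaction_model(d, "res_c", "pas", "gender"), "interaction_p")
  }, numeric(1))
  expect_lt(abs(mean(p_values < 0.05) - 0.05), 0.02)
})

test_that("per-level lasso ranks skip levels smaller than the fold count", {
  d <- pipeline_scores(tiny_config(1500), seed = 22)
  d$age[1:3] <- 75 # make the oldest level tiny
  d$age[-(1:3)] <- sample(20:59, nrow(d) - 3, replace = TRUE)
  expect_warning(
    ranks <- subgroup_lasso_ranks(d, "res_c", "age", nfolds = 10),
    "skipped"
  )
  expect_false("61+" %in% ranks$level)
  rank_cols <- grep("^rank_", names(ranks), value = TRUE)
  for (i in seq_len(nrow(ranks))) {
    expect_setequal(unlist(ranks[i, rank_cols]), 1:9)
  }
})

test_that("level subsetting conserves the analysed rows", {
  d <- pipeline_scores(tiny_config(900), seed = 23)
  tab <- interaction_model(d, "res_c", "pas", "income")
  expect_equal(sum(tab$n), nrow(d))
})

test_that("the sign-consistency audit counts flips and zero-crossings", {
  cells <- tibble::tibble(
    covariate = rep(c("gender", "age"), c(2, 4)),
    factor = "pas",
    level = c("f", "m", "a", "b", "c", "d"),
    beta = c(0.3, 0.2, 0.25, 0.3, -0.05, 0.2),
    lower = c(0.1, 0.05, 0.1, 0.15, -0.2, -0.01),
    upper = c(0.5, 0.35, 0.4, 0.45, 0.1, 0.41)
  )
  audit <- sign_consistency(cells)
  expect_equal(audit$n_cells, 6)
  expect_equal(audit$sign_flips, 1) # the single negative age-level cell
  expect_equal(audit$ci_zero_crossings, 2)

  all_pos <- cells
  all_pos$beta <- abs(all_pos$beta)
  expect_equal(sign_consistency(all_pos)$sign_flips, 0)
})

test_that("a homogeneous generator gives concordant ranks across levels", {
  # independent factors with well-separated weights, identical in every
  # subgroup, so the per-level orderings should agree
  w <- setNames(seq(1.75, 0.15, by = -0.2), resilience_factors())
  cfg <- tiny_config(8000, factor_weights = w,
                     factor_correlation = diag(9),
                     mediation_paths = c(pss_pas = 0, pas_rec = 0))
  d <- pipeline_scores(cfg, seed = 24)
  ranks <- subgroup_lasso_ranks(d, "res_c", "diagnosis", seed = 1)
  rank_cols <- grep("^rank_", names(ranks), value = TRUE)
  r1 <- unlist(ranks[1, rank_cols])
  r2 <- unlist(ranks[2, rank_cols])
  expect_gte(cor(r1, r2, method = "kendall"), 0.7)
})

test_that("the full subgroup table spans levels-by-factors cells", {
  d <- pipeline_scores(tiny_config(2500), seed = 25)
  tab <- subgroup_table(d, "res_c", factors = c("pas", "neu"),
                        covariates = c("gender", "diagnosis"))
  expect_s3_class(tab, "subgroup_table")
  expect_equal(nrow(tab$cells), 2 * 2 + 2 * 2) # 2 covariates x 2 levels x 2 factors
  audit <- sign_consistency(tab)
  expect_equal(audit$n_cells, 8)
})
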