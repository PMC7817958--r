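# Subgroup interaction models, per-level effects, sign-consistency audit,
# and per-level penalized factor ranks.

#' Default subgroup binnings
#'
#' Bins age into 18-30 / 31-45 / 46-60 / 61+ and education years into
#' <13 / 13-16 / 17-20 / 21+, leaves already-categorical covariates alone,
#' and drops the small excluded categories (gender "diverse", diagnosis
#' "not_assessed") by returning `NA` for them so affected rows leave the
#' given analysis.
#'
#' @param data Participant tibble.
#' @param covariate One of `"gender"`, `"age"`, `"country"`, `"income"`,
#'   `"education"`, `"diagnosis"`.
#' @return Factor of subgroup levels (with `NA` for excluded rows).
#' @export
subgroup_levels <- function(data, covariate) {
  switch(covariate,
    age = cut(as.numeric(data$age), c(18, 31, 46, 61, Inf),
              labels = c("18-30", "31-45", "46-60", "61+"), right = FALSE),
    education = cut(data$education_years, c(-Inf, 13, 17, 21, Inf),
                    labels = c("<13", "13-16", "17-20", "21+"),
                    right = FALSE),
    gender = factor(replace(data$gender, data$gender == "diverse", NA),
                    levels = c("female", "male")),
    diagnosis = factor(replace(data$diagnosis,
                               data$diagnosis == "not_assessed", NA),
                       levels = c("no", "yes")),
    country = factor(data$country),
    income = factor(data$income, levels = names(
      default_covariate_distributions()$income
    )),
    stop(sprintf("unknown subgroup covariate '%s'", covariate),
         call. = FALSE)
  )
}

#' Per-level factor effects from an interaction model
#'
#' Fits `outcome ~ base_covariates + covariate + factor + factor:covariate`
#' and reports the factor's slope within each covariate level (main effect
#' plus the level's interaction term, with delta-method SE from the joint
#' covariance), a Wald CI per level, and the overall significance of the
#' interaction block by a likelihood-ratio test against the model without
#' the interaction.
#'
#' @param data Participant tibble.
#' @param outcome Outcome column name.
#' @param factor_name Numeric factor column.
#' @param covariate Subgroup covariate name (binned via
#'   [subgroup_levels()]).
#' @param base_covariates Additional adjustment covariates (the screened
#'   set; the subgroup covariate itself is removed from it if present).
#' @param level Confidence level for per-level CIs (default 0.99).
#' @param min_level_n Levels smaller than this are flagged (default 30).
#' @return A tibble with one row per level: `covariate`, `level`, `n`,
#'   `beta`, `se`, `lower`, `upper`, `small_level`; attributes
#'   `interaction_p` (LR test of the interaction block) and
#'   `interaction_df`.
#' @export
interaction_model <- function(data, outcome, factor_name, covariate,
                              base_covariates = character(0), level = 0.99,
                              min_level_n = 30) {
  base_covariates <- setdiff(base_covariates, covariate)
  d <- data
  d$.group <- subgroup_levels(data, covariate)
  cols <- c(outcome, factor_name, base_covariates, ".group")
  d <- d[complete.cases(d[, cols]), cols]
  d$.group <- droplevels(d$.group)
  levs <- levels(d$.group)
  if (length(levs) < 2) {
    stop(sprintf("covariate '%s' has a single level after exclusions",
                 covariate), call. = FALSE)
  }
  d <- prep_categoricals(d, base_covariates)

  rhs_main <- c(base_covariates, ".group", factor_name)
  fit0 <- lm(build_formula(outcome, rhs_main), data = d)
  fit1 <- lm(build_formula(outcome,
                           c(rhs_main, paste0(factor_name, ":.group"))),
             data = d)
  ll0 <- logLik(fit0)
  ll1 <- logLik(fit1)
  lr_df <- attr(ll1, "df") - attr(ll0, "df")
  lr_p <- pchisq(as.numeric(2 * (ll1 - ll0)), df = lr_df,
                 lower.tail = FALSE)

  cf <- coef(fit1)
  v <- vcov(fit1)
  tq <- qt((1 + level) / 2, df = fit1$df.residual)
  rows <- lapply(levs, function(lv) {
    # lm may canonicalize the interaction label either way round
    int_term <- intersect(
      c(paste0(factor_name, ":.group", lv),
        paste0(".group", lv, ":", factor_name)),
      names(cf)
    )
    if (length(int_term) == 1) {
      beta <- cf[[factor_name]] + cf[[int_term]]
      se <- sqrt(v[factor_name, factor_name] + v[int_term, int_term] +
                   2 * v[factor_name, int_term])
    } else {
      beta <- cf[[factor_name]]
      se <- sqrt(v[factor_name, factor_name])
    }
    n_lv <- sum(d$.group == lv)
    tibble::tibble(
      covariate = covariate, level = lv, n = n_lv, beta = beta, se = se,
      lower = beta - tq * se, upper = beta + tq * se,
      small_level = n_lv < min_level_n
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "interaction_p") <- lr_p
  attr(out, "interaction_df") <- lr_df
  out
}

#' Per-level penalized factor ranks
#'
#' Runs the combined penalized ranking ([lasso_rank()]) separately within
#' each level of a subgroup covariate and reports each level's factor ranks
#' and deviance ratio. Levels with fewer rows than CV folds are skipped with
#' a warning.
#'
#' @inheritParams interaction_model
#' @param factors Factor columns entering the ranking.
#' @param nfolds,seed Passed to [lasso_rank()] (stability repeats are
#'   skipped here; ranks come from the single CV fit per level).
#' @return A tibble: `covariate`, `level`, `n`, one `rank_<factor>` column
#'   per factor, `deviance_ratio`.
#' @export
subgroup_lasso_ranks <- function(data, outcome, covariate,
                                 factors = resilience_factors(),
                                 base_covariates = character(0),
                                 nfolds = 10, seed = 1) {
  base_covariates <- setdiff(base_covariates, covariate)
  group <- subgroup_levels(data, covariate)
  levs <- levels(droplevels(group[!is.na(group)]))
  rows <- lapply(levs, function(lv) {
    d <- data[!is.na(group) & group == lv, ]
    if (nrow(d) < nfolds) {
      warning(sprintf("level '%s' of '%s' has %d rows (< %d folds); skipped",
                      lv, covariate, nrow(d), nfolds), call. = FALSE)
      return(NULL)
    }
    fit <- lasso_rank(d, outcome, factors = factors,
                      covariates = base_covariates, runs = 1,
                      nfolds = nfolds, seed = sub_seed(seed, lv))
    rank_row <- as.data.frame(as.list(fit$ranks))
    names(rank_row) <- paste0("rank_", names(fit$ranks))
    cbind(
      tibble::tibble(covariate = covariate, level = lv, n = fit$n),
      rank_row,
      tibble::tibble(deviance_ratio = fit$deviance_ratio)
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Full subgroup table
#'
#' For every (subgroup covariate, resilience factor) pair, fits the
#' interaction model and collects per-level coefficients with CIs and the
#' interaction-significance flag; optionally adds per-level penalized factor
#' ranks and deviance ratios.
#'
#' @inheritParams interaction_model
#' @param factors Resilience-factor columns.
#' @param covariates Subgroup covariates to span the table.
#' @param alpha Two-tailed significance level for the interaction flag
#'   (default 0.01, the study-wide level).
#' @param include_ranks Also compute per-level penalized ranks.
#' @param nfolds,seed Passed to [subgroup_lasso_ranks()].
#' @return A list of class `subgroup_table` with `cells` (one row per
#'   (covariate level, factor)), and `ranks` (or `NULL`).
#' @export
subgroup_table <- function(data, outcome, factors = resilience_factors(),
                           covariates = c("gender", "age", "country",
                                          "income", "education",
                                          "diagnosis"),
                           base_covariates = character(0), level = 0.99,
                           alpha = 0.01, include_ranks = FALSE,
                           nfolds = 10, seed = 1) {
  cells <- list()
  for (cov in covariates) {
    for (f in factors) {
      tab <- interaction_model(data, outcome, f, cov,
                               base_covariates = base_covariates,
                               level = level)
      tab$factor <- f
      tab$interaction_p <- attr(tab, "interaction_p")
      tab$interaction_significant <- attr(tab, "interaction_p") < alpha
      cells[[length(cells) + 1L]] <- tab
    }
  }
  cells <- tibble::as_tibble(do.call(rbind, cells))
  ranks <- NULL
  if (include_ranks) {
    ranks <- do.call(rbind, lapply(covariates, function(cov) {
      subgroup_lasso_ranks(data, outcome, cov, factors = factors,
                           base_covariates = base_covariates,
                           nfolds = nfolds, seed = seed)
    }))
  }
  structure(list(cells = cells, ranks = ranks, factors = factors,
                 covariates = covariates),
            class = "subgroup_table")
}

#' @export
print.subgroup_table <- function(x, ...) {
  audit <- sign_consistency(x)
  cat("<subgroup_table>", length(x$covariates), "covariates x",
      length(x$factors), "factors;", audit$n_cells, "cells\n")
  cat("  sign flips across levels:", audit$sign_flips, "\n")
  cat("  CIs crossing zero:", audit$ci_zero_crossings, "\n")
  invisible(x)
}

#' Sign-consistency audit of a subgroup table
#'
#' Counts, over all (covariate level, factor) cells: the number of
#' minority-sign coefficients within each (covariate, factor) group (a
#' "sign flip" between levels), and the number of cells whose confidence
#' interval crosses zero.
#'
#' @param table A [subgroup_table()] result (or its `cells` tibble).
#' @return A list: `n_cells`, `sign_flips`, `ci_zero_crossings`.
#' @export
sign_consistency <- function(table) {
  cells <- if (inherits(table, "subgroup_table")) table$cells else table
  flips <- 0L
  for (key in unique(paste(cells$covariate, cells$factor))) {
    b <- cells$beta[paste(cells$covariate, cells$factor) == key]
    s <- sign(b)
    if (length(unique(s[s != 0])) > 1) {
      pos <- sum(s > 0)
      neg <- sum(s < 0)
      flips <- flips + min(pos, neg)
    }
  }
  list(
    n_cells = nrow(cells),
    sign_flips = flips,
    ci_zero_crossings = sum(cells$lower < 0 & cells$upper > 0)
  )
}
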