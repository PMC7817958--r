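# Static figures: forest plot of factor fits, lasso coefficient paths.

#' Forest plot of factor regression coefficients
#'
#' @param factor_fits Tibble from [test_all_factors()].
#' @return A ggplot object.
#' @export
plot_forest <- function(factor_fits) {
  factor_fits$factor <- factor(factor_fits$factor,
                               levels = rev(factor_fits$factor))
  ggplot2::ggplot(factor_fits,
                  ggplot2::aes(x = .data$beta, y = .data$factor)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "regression coefficient (with CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient-path plot of a penalized ranking
#'
#' Coefficient trajectories over the penalty grid, with the selected
#' penalty marked by a vertical broken line.
#'
#' @param lasso A `lasso_result` from [lasso_rank()].
#' @return A ggplot object.
#' @export
plot_lasso_path <- function(lasso) {
  beta <- lasso$beta
  df <- do.call(rbind, lapply(rownames(beta), function(term) {
    data.frame(term = term, lambda = lasso$lambda, beta = beta[term, ],
               is_factor = term %in% lasso$factors)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$beta,
                                   group = .data$term)) +
    ggplot2::geom_line(ggplot2::aes(
      colour = ifelse(.data$is_factor, .data$term, NA_character_)
    )) +
    ggplot2::geom_vline(xintercept = log(lasso$lambda_opt),
                        linetype = "dashed") +
    ggplot2::scale_colour_discrete(na.value = "grey70",
                                   name = "resilience factor") +
    ggplot2::labs(x = "log(penalty)", y = "standardized coefficient") +
    ggplot2::theme_minimal()
}
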