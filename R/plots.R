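#' Plot an AIC surface over the exponent grid
#'
#' One line per language model: regression AIC as a function of the
#' surprisal exponent `k`.
#'
#' @param object An `aic_surface` from [sweep_exponents()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aic_surface <- function(object, ...) {
  df <- tibble::as_tibble(object)[is.finite(object$aic), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$aic,
                                   colour = .data$lm_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "surprisal exponent k", y = "regression AIC",
                  colour = "language model",
                  title = attr(object, "dataset")) +
    ggplot2::theme_minimal()
}

#' Plot the smoothed population-level AIC curve and its minimizer
#'
#' @param object An `exponent_estimate` from [estimate_k()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exponent_estimate <- function(object, ...) {
  ggplot2::ggplot(object$prediction,
                  ggplot2::aes(x = .data$k, y = .data$aic_hat)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k_hat, linetype = "dashed") +
    ggplot2::labs(
      x = "surprisal exponent k", y = "predicted AIC (dummy LM)",
      title = sprintf("k_hat = %g (adj. R^2 = %.2f)%s", object$k_hat,
                      object$fit_quality,
                      if (object$boundary) ", boundary" else "")) +
    ggplot2::theme_minimal()
}

#' Plot pairwise metric contrasts
#'
#' Estimated AIC differences per metric pair, with the conventional
#' substantial-difference threshold at |delta| = 4.
#'
#' @param object A `metric_contrast` tibble from [metric_contrasts()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metric_contrast <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$contrast, y = .data$delta_aic,
                               fill = .data$substantial)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-4, 4), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "estimated AIC difference (a - b)",
                  fill = "|delta| >= 4") +
    ggplot2::theme_minimal()
}

#' Plot a likelihood-ratio battery
#'
#' Chi-squared statistics per test, coloured by FDR-adjusted significance.
#'
#' @param object An `lrt_result` tibble (e.g. from [variance_partition()]).
#' @param alpha Significance threshold on the adjusted p-values.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.lrt_result <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- !is.na(df$p_adjusted) & df$p_adjusted < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$chi2,
                                   fill = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "test (base + added)", y = "chi-squared",
                  fill = sprintf("adj. p < %g", alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
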