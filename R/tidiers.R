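#' Tidy a mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fixed coefficient (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.lmm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$fixed_estimates),
                 estimate = unname(x$fixed_estimates))
}

#' One-row summary of a mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `AIC`, `n_params`, `nobs`, `converged`,
#'   `singular`.
#' @exportS3Method generics::glance
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = x$aic, n_params = x$n_params,
                 nobs = x$nobs, converged = x$converged,
                 singular = x$singular)
}

#' Tidy an exponent estimate
#'
#' @param x An `exponent_estimate`.
#' @param ... Unused.
#' @return The dummy-model prediction curve (`k`, `aic_hat`).
#' @exportS3Method generics::tidy
tidy.exponent_estimate <- function(x, ...) {
  x$prediction
}

#' One-row summary of an exponent estimate
#'
#' @param x An `exponent_estimate`.
#' @param ... Unused.
#' @return Tibble with `k_hat`, `boundary`, `fit_quality`, `pooled`,
#'   `n_lms`.
#' @exportS3Method generics::glance
glance.exponent_estimate <- function(x, ...) {
  tibble::tibble(k_hat = x$k_hat, boundary = x$boundary,
                 fit_quality = x$fit_quality, pooled = x$pooled,
                 n_lms = x$n_lms)
}
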