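#' Fit a linear mixed-effects model by maximum likelihood
#'
#' All fits use ML (not REML) so that log-likelihoods, AICs and
#' likelihood-ratio tests are comparable across models differing in their
#' fixed effects. Optimizer settings are frozen (bobyqa, no derivative
#' check) so a fit is deterministic given the data. Singular fits are
#' flagged, not rejected.
#'
#' @param design An `lmm_design` from [build_design()], or a data frame (in
#'   which case `formula` must be supplied).
#' @param formula Mixed-model formula when `design` is a plain data frame.
#'
#' @return An object of class `lmm_fit`: `logLik`, `n_params` (fixed
#'   coefficients + variance/covariance parameters + residual), `aic`,
#'   `fixed_estimates`, `converged`, `singular`, `nobs`, and the underlying
#'   `merMod` as `$model`.
#' @export
fit_lmm <- function(design, formula = NULL) {
  if (inherits(design, "lmm_design")) {
    data <- design$data
    formula <- formula %||% design$formula
  } else {
    data <- design
    if (is.null(formula)) abort("supply a formula with a plain data frame")
  }

  fixed_fml <- lme4::nobars(formula)
  mm <- model.matrix(fixed_fml, data = data)
  if (qr(mm)$rank < ncol(mm)) {
    abort("rank-deficient fixed-effect design")
  }
  for (grp in all.vars(formula)) {
    if (is.factor(data[[grp]]) && nlevels(droplevels(data[[grp]])) < 2L &&
        grp %in% vapply(lme4::findbars(formula),
                        function(b) deparse(b[[3]]), character(1))) {
      abort(paste0("grouping factor '", grp, "' has a single level"))
    }
  }

  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(
                 optimizer = "bobyqa", calc.derivs = FALSE,
                 optCtrl = list(maxfun = 100000),
                 # singularity is reported via the $singular flag instead
                 check.conv.singular = lme4::.makeCC(action = "ignore",
                                                     tol = 1e-4))),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    converged <- FALSE
  }
  if (!converged) warn("mixed-model fit did not converge cleanly")

  ll <- logLik(fit)
  n_params <- attr(ll, "df")
  structure(
    list(
      logLik = as.numeric(ll),
      n_params = n_params,
      aic = 2 * n_params - 2 * as.numeric(ll),
      fixed_estimates = lme4::fixef(fit),
      converged = converged,
      singular = lme4::isSingular(fit),
      nobs = stats::nobs(fit),
      formula = formula,
      model = fit
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> logLik ", format(x$logLik), ", AIC ", format(x$aic),
      ", ", x$n_params, " params, n = ", x$nobs, "\n", sep = "")
  if (x$singular) cat("  (singular fit)\n")
  if (!x$converged) cat("  (did not converge)\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' @param base,augmented `lmm_fit` objects sharing the same response and
#'   random structure, with the augmented model's fixed terms a superset of
#'   the base model's.
#' @param df Degrees of freedom (number of added fixed terms); inferred from
#'   the fixed-coefficient names when omitted.
#' @param label Test label, conventionally `"base + added"`.
#'
#' @return A one-row tibble of class `lrt_result`: `label`, `chi2`, `df`,
#'   `p_raw`, `p_adjusted` (`NA` until an FDR family is applied).
#' @export
likelihood_ratio <- function(base, augmented, df = NULL, label = NULL) {
  stopifnot(inherits(base, "lmm_fit"), inherits(augmented, "lmm_fit"))
  if (base$nobs != augmented$nobs) {
    abort("models fit to different numbers of observations")
  }
  base_terms <- names(base$fixed_estimates)
  aug_terms <- names(augmented$fixed_estimates)
  if (!all(base_terms %in% aug_terms)) {
    abort("models are not nested: base fixed terms not a subset of augmented")
  }
  added <- setdiff(aug_terms, base_terms)
  df <- df %||% length(added)
  chi2 <- 2 * (augmented$logLik - base$logLik)
  if (chi2 < -1e-6) {
    warn(sprintf(
      "augmented logLik below base by %.3g: optimizer failure; chi2 set to 0",
      -chi2 / 2))
  }
  chi2 <- max(0, chi2)
  out <- tibble::tibble(
    label = label %||% paste(c("base", added), collapse = " + "),
    chi2 = chi2,
    df = as.integer(df),
    p_raw = pchisq(chi2, df = df, lower.tail = FALSE),
    p_adjusted = NA_real_
  )
  class(out) <- c("lrt_result", class(out))
  out
}

#' Variance-partitioning likelihood-ratio battery
#'
#' Tests whether each of probability (P), surprisal (S) and S^0.6 explains
#' variance in N400 amplitude beyond the others, via eight likelihood-ratio
#' tests between nested mixed models sharing the dataset's recipe:
#' `S^0.6 + S`, `S^0.6 + P`, `S + S^0.6`, `S + P`, `P + S`, `P + S^0.6`,
#' `(S + P) + S^0.6` (all df 1) and `S^0.6 + (S + P)` (df 2). A label reads
#' "base + added": `S + P` asks whether probability explains variance beyond
#' surprisal.
#'
#' @param dataset An [n400_dataset()].
#' @param metrics Data frame with columns `item_id`, `P`, `S`, `S06` (raw
#'   metric values per item; z-scored internally).
#' @param fdr Apply Benjamini-Yekutieli correction across the battery
#'   (default `TRUE`). Use `FALSE` to merge the battery into a wider family.
#'
#' @return An 8-row `lrt_result` tibble.
#' @export
variance_partition <- function(dataset, metrics, fdr = TRUE) {
  stopifnot(inherits(dataset, "n400_dataset"),
            all(c("item_id", "P", "S", "S06") %in% names(metrics)))
  usable <- metrics[is.finite(metrics$P) & is.finite(metrics$S) &
                      is.finite(metrics$S06), ]
  design <- build_design(dataset,
                         metric = data.frame(item_id = usable$item_id,
                                             value = usable$S))
  data <- design$data
  idx <- match(as.character(data$item_id), usable$item_id)
  data$S <- data$metric
  data$P <- zscore(usable$P[idx])
  data$S06 <- zscore(usable$S06[idx])

  other_fixed <- setdiff(design$fixed_terms, "metric")
  random_parts <- vapply(dataset$recipe$random_terms, function(rt) {
    lhs <- paste(c(if (rt$intercept) "1" else "0", rt$slopes), collapse = " + ")
    paste0("(", lhs, " | ", rt$group, ")")
  }, character(1))
  fit_set <- function(metric_terms) {
    fml <- as.formula(paste(
      "response ~",
      paste(c(metric_terms, other_fixed, random_parts), collapse = " + ")
    ))
    fit_lmm(data, formula = fml)
  }

  battery <- list(
    list(label = "S^0.6 + S",         base = "S06",             aug = c("S06", "S"),      df = 1L),
    list(label = "S^0.6 + P",         base = "S06",             aug = c("S06", "P"),      df = 1L),
    list(label = "S + S^0.6",         base = "S",               aug = c("S", "S06"),      df = 1L),
    list(label = "S + P",             base = "S",               aug = c("S", "P"),        df = 1L),
    list(label = "P + S",             base = "P",               aug = c("P", "S"),        df = 1L),
    list(label = "P + S^0.6",         base = "P",               aug = c("P", "S06"),      df = 1L),
    list(label = "(S + P) + S^0.6",   base = c("S", "P"),       aug = c("S", "P", "S06"), df = 1L),
    list(label = "S^0.6 + (S + P)",   base = "S06",             aug = c("S06", "S", "P"), df = 2L)
  )

  # each distinct fixed-term set is fitted once and reused across tests
  needed <- unique(unlist(lapply(battery, function(b)
    list(paste(b$base, collapse = ","), paste(b$aug, collapse = ","))),
    use.names = FALSE))
  fits <- lapply(setNames(needed, needed), function(key) {
    terms <- strsplit(key, ",")[[1]]
    tryCatch(fit_set(terms), error = function(e) e)
  })

  out <- purrr::map_dfr(battery, function(b) {
    fb <- fits[[paste(b$base, collapse = ",")]]
    fa <- fits[[paste(b$aug, collapse = ",")]]
    for (f in list(fb, fa)) {
      if (inherits(f, "error")) {
        abort(paste0("test '", b$label, "': ", conditionMessage(f)))
      }
    }
    likelihood_ratio(fb, fa, df = b$df, label = b$label)
  })
  if (fdr) out$p_adjusted <- by_fdr(out$p_raw)
  class(out) <- c("lrt_result", class(tibble::tibble()))
  out
}

#' Benjamini-Yekutieli false discovery rate adjustment
#'
#' Step-up FDR correction valid under arbitrary dependence, inflating the
#' Benjamini-Hochberg adjustment by `c(m) = sum(1/i, i = 1..m)`. Input order
#' is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
by_fdr <- function(p_values) {
  if (!is.numeric(p_values)) abort("p-values must be numeric")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BY")
}
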