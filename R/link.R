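#' Default exponent grid for the surprisal power sweep
#'
#' All 0.1 increments between 0.1 and 2, plus -1, -0.5 and -0.1 for
#' comparison. Negative exponents feed the AIC surface and plots but are
#' excluded from exponent estimation, which predicts only over `[0, 2]`.
#'
#' @return Sorted numeric vector of exponents.
#' @export
default_exponent_grid <- function() {
  sort(c(-1, -0.5, -0.1, seq(0.1, 2, by = 0.1)))
}

#' Sweep surprisal exponents and record regression AIC per language model
#'
#' For every backend and every exponent `k` on the grid, fits the dataset's
#' recipe with z-scored `S^k` as the metric and records the ML AIC. Cells
#' whose fit fails are recorded as `NA` with the failure reason; a surface
#' with more than 10% failed cells is marked unreliable.
#'
#' @param dataset An [n400_dataset()].
#' @param scores Tibble with columns `item_id`, `lm_id`, `surprisal` (one
#'   row per item per backend; natural-log surprisal).
#' @param grid Exponent grid (default [default_exponent_grid()]).
#'
#' @return A tibble of class `aic_surface` with columns `lm_id`, `k`, `aic`,
#'   `error`; attributes `dataset` (name), `grid`, `unreliable`.
#' @export
sweep_exponents <- function(dataset, scores, grid = default_exponent_grid()) {
  stopifnot(inherits(dataset, "n400_dataset"),
            all(c("item_id", "lm_id", "surprisal") %in% names(scores)))
  if (length(grid) < 1L || anyDuplicated(grid)) {
    abort("grid must be a non-empty set of distinct exponents")
  }
  lm_ids <- unique(scores$lm_id)
  if (anyDuplicated(paste(scores$lm_id, scores$item_id)) > 0) {
    abort("duplicate (lm_id, item_id) rows in scores")
  }

  out <- purrr::map_dfr(lm_ids, function(lm) {
    sc <- scores[scores$lm_id == lm, ]
    # one design per backend; each k swaps in a re-standardized metric column
    base <- build_design(dataset,
                         metric = data.frame(item_id = sc$item_id,
                                             value = sc$surprisal))
    data <- base$data
    s_item <- sc$surprisal[match(as.character(data$item_id), sc$item_id)]
    purrr::map_dfr(grid, function(k) {
      res <- tryCatch({
        data$metric <- zscore(s_item^k)
        fit <- fit_lmm(data, formula = base$formula)
        list(aic = fit$aic, error = NA_character_)
      }, error = function(e) list(aic = NA_real_,
                                  error = conditionMessage(e)))
      tibble::tibble(lm_id = lm, k = k, aic = res$aic, error = res$error)
    })
  })
  structure(out,
            class = c("aic_surface", class(tibble::tibble())),
            dataset = dataset$name,
            grid = sort(grid),
            unreliable = mean(is.na(out$aic)) > 0.10)
}

#' Estimate the best-fitting surprisal exponent from an AIC surface
#'
#' Fits a generalized additive model `AIC ~ s(k) + s(lm, bs = "re")` — a
#' thin-plate penalized spline over the exponent with a random offset per
#' language model, wiggliness selected by marginal (REML) likelihood — then
#' predicts the population-level AIC curve for a dummy (non-existent)
#' language model over `k = 0, 0.1, ..., 2` and takes the minimizer.
#'
#' @param surface An `aic_surface` from [sweep_exponents()]. For
#'   `pooled = TRUE` supply a surface with an additional `dataset` column
#'   (e.g. several surfaces row-bound together); a per-dataset random offset
#'   is then added and one global curve is estimated.
#' @param pooled Estimate one exponent across datasets.
#' @param basis_dim Spline basis dimension (capped at the number of distinct
#'   grid values).
#'
#' @return An object of class `exponent_estimate`: `k_hat`, `boundary`
#'   (logical; `k_hat` on the edge of `[0, 2]`), `fit_quality` (adjusted
#'   R-squared of the smoother), `pooled`, `n_lms`, `prediction` (tibble of
#'   the dummy-model curve), and the fitted `gam`.
#' @export
estimate_k <- function(surface, pooled = FALSE, basis_dim = 10) {
  stopifnot(is.data.frame(surface),
            all(c("lm_id", "k", "aic") %in% names(surface)))
  if (pooled && !"dataset" %in% names(surface)) {
    abort("pooled estimation needs a 'dataset' column on the surface")
  }
  # negative exponents are computed for surface completeness only; the
  # estimation grid is [0, 2], so the smoother is fitted on that range
  cells <- surface[is.finite(surface$aic) & surface$k > 0, , drop = FALSE]
  n_lms <- dplyr::n_distinct(cells$lm_id)
  if (n_lms < 2L) abort("exponent estimation needs >= 2 language models")
  if (dplyr::n_distinct(cells$k) < 5L) {
    abort("exponent estimation needs >= 5 valid grid points")
  }
  if (sd(cells$aic) == 0) abort("degenerate surface: all AICs equal")

  df <- data.frame(aic = cells$aic, k = cells$k,
                   lm_id = factor(cells$lm_id))
  k_basis <- min(basis_dim, dplyr::n_distinct(df$k))
  fml <- aic ~ s(k, bs = "tp", k = k_basis) + s(lm_id, bs = "re")
  exclude <- "s(lm_id)"
  if (pooled) {
    df$dataset <- factor(cells$dataset)
    fml <- aic ~ s(k, bs = "tp", k = k_basis) + s(lm_id, bs = "re") +
      s(dataset, bs = "re")
    exclude <- c("s(lm_id)", "s(dataset)")
  }
  gam_fit <- mgcv::gam(fml, data = df, method = "REML")

  pred_grid <- seq(0, 2, by = 0.1)
  newdata <- data.frame(k = pred_grid, lm_id = df$lm_id[1])
  if (pooled) newdata$dataset <- df$dataset[1]
  curve <- as.numeric(predict(gam_fit, newdata = newdata, exclude = exclude))
  k_hat <- pred_grid[which.min(curve)]

  structure(
    list(
      k_hat = k_hat,
      boundary = k_hat %in% range(pred_grid),
      fit_quality = summary(gam_fit)$r.sq,
      pooled = pooled,
      n_lms = n_lms,
      grid = pred_grid,
      prediction = tibble::tibble(k = pred_grid, aic_hat = curve),
      gam = gam_fit,
      dataset = if (pooled) "pooled" else attr(surface, "dataset") %||% NA_character_
    ),
    class = "exponent_estimate"
  )
}

#' @export
print.exponent_estimate <- function(x, ...) {
  cat("<exponent_estimate> k_hat = ", format(x$k_hat),
      if (x$boundary) " (boundary)", ", adj. R^2 = ",
      format(round(x$fit_quality, 3)), ", ", x$n_lms, " LMs",
      if (x$pooled) ", pooled", "\n", sep = "")
  invisible(x)
}

#' Pairwise metric contrasts in regression AIC across language models
#'
#' For each pair of metrics, estimates the difference in regression AIC from
#' a linear mixed-effects model with AIC as the dependent variable, metric
#' as the predictor and language model as a random intercept. In a balanced
#' complete table this equals the mean paired AIC difference. A contrast is
#' "substantial" when the estimated |difference| is at least 4 (compared at
#' a numerical tolerance of 1e-8 so exact-boundary tables flag correctly).
#' A companion
#' likelihood-ratio test checks metric as a predictor of AIC.
#'
#' @param aic_table Tibble with columns `lm_id`, `metric`, `aic`, complete
#'   over every (backend, metric) cell.
#' @param metrics Metric labels in display order (default: order of
#'   appearance). Contrast `"a-b"` reports `delta_aic` = AIC(a) - AIC(b),
#'   positive meaning b fits better.
#'
#' @return A tibble of class `metric_contrast`: `contrast`, `metric_a`,
#'   `metric_b`, `delta_aic`, `substantial`, `chi2`, `df`, `p_raw`,
#'   `p_adjusted`.
#' @export
metric_contrasts <- function(aic_table, metrics = unique(aic_table$metric)) {
  stopifnot(all(c("lm_id", "metric", "aic") %in% names(aic_table)))
  aic_table <- aic_table[aic_table$metric %in% metrics, ]
  cells <- tidyr::expand_grid(lm_id = unique(aic_table$lm_id),
                              metric = metrics)
  have <- paste(aic_table$lm_id, aic_table$metric)
  missing_cells <- cells[!paste(cells$lm_id, cells$metric) %in% have, ]
  if (nrow(missing_cells) > 0L) {
    abort(paste0("missing AIC cells: ",
                 paste(paste0("(", missing_cells$lm_id, ", ",
                              missing_cells$metric, ")"), collapse = ", ")))
  }
  if (anyDuplicated(have) > 0) abort("duplicate (lm_id, metric) cells")

  n_lms <- dplyr::n_distinct(aic_table$lm_id)
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    sub <- aic_table[aic_table$metric %in% pr, ]
    sub$metric <- factor(sub$metric, levels = pr)
    if (n_lms >= 2L) {
      full <- fit_lmm(data.frame(aic = sub$aic, metric = sub$metric,
                                 lm_id = factor(sub$lm_id)),
                      formula = aic ~ metric + (1 | lm_id))
      null <- fit_lmm(data.frame(aic = sub$aic, lm_id = factor(sub$lm_id)),
                      formula = aic ~ 1 + (1 | lm_id))
      delta <- -unname(full$fixed_estimates[2])   # AIC(a) - AIC(b)
      lrt <- likelihood_ratio(null, full, df = 1,
                              label = paste0(a, "-", b))
      chi2 <- lrt$chi2; p_raw <- lrt$p_raw
    } else {
      delta <- sub$aic[sub$metric == a] - sub$aic[sub$metric == b]
      chi2 <- NA_real_; p_raw <- NA_real_
    }
    tibble::tibble(
      contrast = paste0(a, "-", b),
      metric_a = a, metric_b = b,
      delta_aic = delta,
      substantial = abs(delta) >= 4 - 1e-8,
      chi2 = chi2, df = if (n_lms >= 2L) 1L else NA_integer_,
      p_raw = p_raw, p_adjusted = NA_real_
    )
  }) |>
    structure(class = c("metric_contrast", class(tibble::tibble())))
}
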