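make_surface <- function(df, dataset = "toy", grid = sort(unique(df$k))) {
  structure(tibble::as_tibble(df),
            class = c("aic_surface", class(tibble::tibble())),
            dataset = dataset, grid = grid, unreliable = FALSE)
}

test_that("sweep_exponents covers the grid and validates inputs", {
  b <- simulate_n400(sim_config(n_subjects = 10, n_items = 24,
                                n_mock_lms = 2, seed = 31))
  grid <- seq(0.2, 1, 0.2)
  surf <- sweep_exponents(b$dataset, b$scores, grid = grid)
  expect_equal(nrow(surf), 2 * length(grid))
  expect_true(all(is.finite(surf$aic)))
  expect_false(attr(surf, "unreliable"))

  dup <- dplyr::bind_rows(b$scores, b$scores[1, ])
  expect_error(sweep_exponents(b$dataset, dup, grid = grid), "duplicate")
  expect_error(sweep_exponents(b$dataset, b$scores, grid = numeric(0)),
               "grid")
})

test_that("per-LM AIC argmin finds the generating exponent at low noise", {
  b <- simulate_n400(sim_config(k_true = 0.5, lm_noise_sd = 0,
                                sd_residual = 0.3, sd_item = 0,
                                sd_subject = 0.2, n_mock_lms = 2,
                                seed = 77))
  surf <- sweep_exponents(b$dataset, b$scores,
                          grid = seq(0.1, 2, by = 0.1))
  argmins <- surf |>
    dplyr::group_by(.data$lm_id) |>
    dplyr::slice_min(.data$aic, n = 1)
  expect_true(all(abs(argmins$k - 0.5) <= 0.1 + 1e-9))
})

test_that("estimate_k recovers an exact on-grid quadratic minimum", {
  grid <- seq(0.1, 2, by = 0.1)
  df <- tidyr::expand_grid(lm_id = sprintf("lm%d", 1:3), k = grid) |>
    dplyr::mutate(aic = 100 * (k - 0.6)^2 +
                    c(lm1 = 0, lm2 = 30, lm3 = -20)[lm_id])
  est <- estimate_k(make_surface(df))
  expect_equal(est$k_hat, 0.6)
  expect_false(est$boundary)
  expect_gt(est$fit_quality, 0.99)
  expect_equal(est$grid, seq(0, 2, by = 0.1))
  expect_true(est$k_hat %in% est$grid)
})

test_that("monotone-decreasing surfaces give a flagged boundary estimate", {
  grid <- seq(0.1, 2, by = 0.1)
  df <- tidyr::expand_grid(lm_id = c("a", "b"), k = grid) |>
    dplyr::mutate(aic = 500 - 40 * k + ifelse(lm_id == "a", 0, 10))
  est <- estimate_k(make_surface(df))
  expect_equal(est$k_hat, 2)
  expect_true(est$boundary)
})

test_that("estimate_k enforces its preconditions", {
  grid <- seq(0.1, 2, by = 0.1)
  one_lm <- tidyr::expand_grid(lm_id = "only", k = grid) |>
    dplyr::mutate(aic = (k - 1)^2)
  expect_error(estimate_k(make_surface(one_lm)), ">= 2 language models")
  few_k <- tidyr::expand_grid(lm_id = c("a", "b"), k = c(0.5, 1, 1.5)) |>
    dplyr::mutate(aic = (k - 1)^2)
  expect_error(estimate_k(make_surface(few_k)), ">= 5 valid grid points")
  flat <- tidyr::expand_grid(lm_id = c("a", "b"), k = grid) |>
    dplyr::mutate(aic = 7)
  expect_error(estimate_k(make_surface(flat)), "degenerate")
})

test_that("smoothed k_hat stays within a grid step under noise (property)", {
  grid <- seq(0.1, 2, by = 0.1)
  base <- tidyr::expand_grid(lm_id = sprintf("lm%02d", 1:10), k = grid)
  curve <- 100 * (grid[which.min(abs(grid - 0.6))] - grid)^2
  noise_sd <- 0.05 * diff(range(100 * (grid - 0.6)^2))
  set.seed(2024)
  hits <- replicate(200, {
    df <- base |>
      dplyr::mutate(aic = 100 * (k - 0.6)^2 +
                      rep(rnorm(10, 0, 25), each = length(grid)) +
                      rnorm(dplyr::n(), 0, noise_sd))
    abs(estimate_k(make_surface(df))$k_hat - 0.6) <= 0.1 + 1e-9
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a constant AIC offset on one LM is absorbed by its random term", {
  grid <- seq(0.1, 2, by = 0.1)
  df <- tidyr::expand_grid(lm_id = sprintf("lm%d", 1:4), k = grid) |>
    dplyr::mutate(aic = 80 * (k - 0.8)^2 +
                    c(lm1 = 5, lm2 = -5, lm3 = 0, lm4 = 10)[lm_id])
  base_hat <- estimate_k(make_surface(df))$k_hat
  df2 <- dplyr::mutate(df, aic = aic + ifelse(lm_id == "lm2", 250, 0))
  shifted_hat <- estimate_k(make_surface(df2))$k_hat
  expect_lte(abs(shifted_hat - base_hat), 0.1 + 1e-9)
})

test_that("metric_contrasts equals mean paired differences on balanced tables", {
  set.seed(8)
  lms <- sprintf("lm%d", 1:6)
  offsets <- rnorm(6, 0, 20)
  tbl <- dplyr::bind_rows(
    tibble::tibble(lm_id = lms, metric = "P", aic = 1000 + offsets + rnorm(6)),
    tibble::tibble(lm_id = lms, metric = "S", aic = 985 + offsets + rnorm(6)),
    tibble::tibble(lm_id = lms, metric = "S^0.6",
                   aic = 980 + offsets + rnorm(6))
  )
  res <- metric_contrasts(tbl, metrics = c("P", "S", "S^0.6"))
  expect_equal(res$contrast, c("P-S", "P-S^0.6", "S-S^0.6"))
  wide <- tidyr::pivot_wider(tbl, names_from = "metric", values_from = "aic")
  expect_equal(res$delta_aic[1], mean(wide$P - wide$S), tolerance = 1e-6)
  expect_equal(res$delta_aic[2], mean(wide$P - wide$`S^0.6`),
               tolerance = 1e-6)
  expect_equal(res$delta_aic[3], mean(wide$S - wide$`S^0.6`),
               tolerance = 1e-6)
  expect_true(all(is.finite(res$chi2)))
})

test_that("single-LM contrasts fall back to the raw difference", {
  tbl <- tibble::tibble(lm_id = "only", metric = c("P", "S"),
                        aic = c(100, 90))
  res <- metric_contrasts(tbl, metrics = c("P", "S"))
  expect_equal(res$delta_aic, 10)
  expect_true(is.na(res$chi2))
})

test_that("the substantial flag flips exactly at |delta AIC| = 4", {
  lms <- sprintf("lm%d", 1:4)
  offsets <- c(0, 12, -7, 3)
  at4 <- dplyr::bind_rows(
    tibble::tibble(lm_id = lms, metric = "a", aic = 900 + offsets),
    tibble::tibble(lm_id = lms, metric = "b", aic = 896 + offsets)
  )
  expect_true(metric_contrasts(at4, metrics = c("a", "b"))$substantial)
  under <- dplyr::mutate(at4, aic = ifelse(metric == "b", aic + 0.5, aic))
  expect_false(metric_contrasts(under, metrics = c("a", "b"))$substantial)
})

test_that("metric_contrasts reports missing cells", {
  tbl <- tibble::tibble(lm_id = c("x", "x", "y"),
                        metric = c("P", "S", "P"), aic = 1:3)
  expect_error(metric_contrasts(tbl, metrics = c("P", "S")), "\\(y, S\\)")
})
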