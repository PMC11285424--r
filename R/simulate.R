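#' Configuration for the synthetic N400 generator
#'
#' Defines the generating model for a fully synthetic study: item-level true
#' probabilities with log-uniform surprisal, several mock language models
#' observing those probabilities with noise, trial amplitudes driven by a
#' known link function plus baseline, covariates, crossed subject/item
#' random effects and Gaussian noise, cloze values tied monotonically to
#' S^0.6, and mock embeddings with a configurable similarity-surprisal
#' correlation.
#'
#' @param link Generating link: `"powered_surprisal"` (amplitude driven by
#'   `S^k_true`) or `"probability"`.
#' @param k_true Generating exponent for the powered-surprisal link.
#' @param beta0,beta_metric,beta_baseline Fixed-effect coefficients on the
#'   (standardized) predictors. `beta_metric` is negative by default: more
#'   surprising words elicit more negative amplitudes.
#' @param beta_covariates Named coefficients for the item-level covariates.
#' @param sd_subject,sd_item,sd_residual Random-effect and residual SDs (µV).
#' @param n_subjects,n_items,n_labs Design size; subjects are assigned to
#'   labs round-robin with a small additive lab offset.
#' @param surprisal_range True item surprisal is log-uniform on this range
#'   (nats).
#' @param n_mock_lms Number of mock language models.
#' @param lm_noise_sd SD of the Gaussian noise each mock LM adds to the item
#'   log-probability (nats).
#' @param cloze_noise SD of the noise linking cloze to standardized S^0.6.
#' @param similarity_target Target correlation between contextual similarity
#'   and true surprisal (negative: more similar words are less surprising).
#' @param embedding_dim Dimension of the mock embeddings.
#' @param lab_offset_sd SD of the per-lab additive offsets.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(link = c("powered_surprisal", "probability"),
                       k_true = 0.6,
                       beta0 = 0, beta_metric = -1, beta_baseline = 0.25,
                       beta_covariates = c(concreteness = 0.05,
                                           log_frequency = 0.05,
                                           old20 = 0.05,
                                           sentence_position = 0.05),
                       sd_subject = 0.5, sd_item = 0.1, sd_residual = 0.75,
                       n_subjects = 30, n_items = 60, n_labs = 3,
                       surprisal_range = c(0.5, 12),
                       n_mock_lms = 5, lm_noise_sd = 0.1,
                       cloze_noise = 0.1, similarity_target = -0.5,
                       embedding_dim = 10, lab_offset_sd = 0.3,
                       seed = 1) {
  link <- match.arg(link)
  if (any(c(sd_subject, sd_item, sd_residual, lm_noise_sd, cloze_noise,
            lab_offset_sd) < 0)) {
    abort("all noise SDs must be >= 0")
  }
  stopifnot(n_labs >= 1, n_mock_lms >= 1, embedding_dim >= 2,
            length(surprisal_range) == 2, surprisal_range[1] > 0,
            surprisal_range[2] > surprisal_range[1],
            abs(similarity_target) < 1, is.finite(k_true))
  if (n_subjects * n_items < 20) {
    abort("design too small: n_subjects * n_items must be >= 20")
  }
  structure(
    list(link = link, k_true = k_true, beta0 = beta0,
         beta_metric = beta_metric, beta_baseline = beta_baseline,
         beta_covariates = beta_covariates, sd_subject = sd_subject,
         sd_item = sd_item, sd_residual = sd_residual,
         n_subjects = n_subjects, n_items = n_items, n_labs = n_labs,
         surprisal_range = surprisal_range, n_mock_lms = n_mock_lms,
         lm_noise_sd = lm_noise_sd, cloze_noise = cloze_noise,
         similarity_target = similarity_target,
         embedding_dim = embedding_dim, lab_offset_sd = lab_offset_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic study bundle with known ground truth
#'
#' Draws one complete synthetic study under a [sim_config()]:
#' `amplitude = beta0 + beta_metric * z(link) + beta_baseline * z(baseline)
#' + sum(beta_cov * z(cov)) + lab offset + subject + item + residual`.
#' Each mock LM reports the item probability perturbed by Gaussian noise on
#' the log scale (results at or above probability 1 are clipped to a minimum
#' surprisal of 0.01 nats). Cloze is a noisy decreasing function of
#' standardized S^0.6, clamped to `[0, 1]`. Embeddings are constructed so
#' each item's contextual similarity is exact by construction and correlates
#' with true surprisal at the configured target.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `sim_bundle`:
#' \describe{
#'   \item{dataset}{[n400_dataset()] of trials under the
#'     `lab_random_subject` recipe (baseline and covariate columns are
#'     present, so the `baseline_covariates` recipe also applies).}
#'   \item{stimuli}{Tibble `item_id`, `context`, `critical_word`, `cloze`.}
#'   \item{scores}{Tibble `lm_id`, `item_id`, `probability`, `surprisal`
#'     (natural log) for every mock LM.}
#'   \item{embeddings}{Mock [embedding_provider()].}
#'   \item{similarity}{Tibble `item_id`, `similarity` (the exact cosine of
#'     each item, also recoverable through [contextual_similarity()]).}
#'   \item{truth}{Generating parameters and latent draws.}
#' }
#' @export
simulate_n400 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_i <- config$n_items; n_s <- config$n_subjects

  item_id <- sprintf("i%03d", seq_len(n_i))
  subject_id <- sprintf("s%03d", seq_len(n_s))

  s_true <- exp(runif(n_i, log(config$surprisal_range[1]),
                      log(config$surprisal_range[2])))
  p_true <- exp(-s_true)
  link_val <- if (config$link == "probability") p_true else
    s_true^config$k_true

  covs <- lapply(config$beta_covariates, function(b) rnorm(n_i))
  names(covs) <- names(config$beta_covariates)

  lab_of_subject <- sprintf("lab%d",
                            ((seq_len(n_s) - 1L) %% config$n_labs) + 1L)
  lab_offsets <- rnorm(config$n_labs, 0, config$lab_offset_sd)
  names(lab_offsets) <- sprintf("lab%d", seq_len(config$n_labs))
  b_subject <- rnorm(n_s, 0, config$sd_subject)
  b_item <- rnorm(n_i, 0, config$sd_item)

  trials <- tidyr::expand_grid(subject = seq_len(n_s), item = seq_len(n_i))
  n_t <- nrow(trials)
  baseline <- rnorm(n_t)
  eps <- rnorm(n_t, 0, config$sd_residual)

  # predictors are standardized over the expanded trial vectors — exactly
  # the columns the fitted regressions standardize — so noiseless recovery
  # of the generating coefficients is exact
  fixed_trial <- config$beta_metric * zscore(link_val[trials$item])
  for (nm in names(covs)) {
    fixed_trial <- fixed_trial +
      config$beta_covariates[[nm]] * zscore(covs[[nm]][trials$item])
  }
  amplitude <- config$beta0 +
    fixed_trial +
    config$beta_baseline * zscore(baseline) +
    lab_offsets[lab_of_subject[trials$subject]] +
    b_subject[trials$subject] + b_item[trials$item] + eps

  trial_tbl <- tibble::tibble(
    subject_id = subject_id[trials$subject],
    item_id = item_id[trials$item],
    lab = lab_of_subject[trials$subject],
    amplitude = amplitude,
    baseline = baseline,
    concreteness = covs$concreteness[trials$item] %||% rep(0, n_t),
    log_frequency = covs$log_frequency[trials$item] %||% rep(0, n_t),
    old20 = covs$old20[trials$item] %||% rep(0, n_t),
    sentence_position = covs$sentence_position[trials$item] %||% rep(0, n_t)
  )

  # mock LMs: noisy log-probability, clipped away from p = 1
  scores <- purrr::map_dfr(seq_len(config$n_mock_lms), function(m) {
    s_obs <- pmax(s_true + rnorm(n_i, 0, config$lm_noise_sd), 0.01)
    tibble::tibble(lm_id = sprintf("lm%02d", m), item_id = item_id,
                   probability = exp(-s_obs), surprisal = s_obs)
  })

  cloze <- pmin(pmax(
    0.45 - 0.25 * zscore(s_true^0.6) + rnorm(n_i, 0, config$cloze_noise),
    0), 1)

  # similarity values hit the target correlation with S by construction
  t_r <- config$similarity_target
  sim_val <- pmin(pmax(
    0.4 * (t_r * zscore(s_true) + sqrt(1 - t_r^2) * rnorm(n_i)),
    -0.95), 0.95)

  d <- config$embedding_dim
  unit <- function(v) v / sqrt(sum(v^2))
  emb_table <- list()
  for (i in seq_len(n_i)) {
    u <- unit(rnorm(d))
    r <- rnorm(d); r <- unit(r - sum(r * u) * u)
    v <- sim_val[i] * u + sqrt(1 - sim_val[i]^2) * r
    jitter <- 0.1 * unit(rnorm(d))
    emb_table[[paste0("ctx", item_id[i], "a")]] <- u + jitter
    emb_table[[paste0("ctx", item_id[i], "b")]] <- u - jitter
    emb_table[[paste0("ctx", item_id[i], "c")]] <- u
    emb_table[[paste0("crit", item_id[i])]] <- v
  }

  stimuli <- tibble::tibble(
    item_id = item_id,
    context = paste0("ctx", item_id, "a ctx", item_id, "b ctx", item_id, "c"),
    critical_word = paste0("crit", item_id),
    cloze = cloze
  )

  structure(
    list(
      dataset = n400_dataset(trial_tbl, name = "synthetic",
                             recipe = preset_recipe("lab_random_subject")),
      stimuli = stimuli,
      scores = scores,
      embeddings = mock_embeddings(emb_table, id = "mock-synthetic"),
      similarity = tibble::tibble(item_id = item_id, similarity = sim_val),
      truth = list(
        k_true = config$k_true, link = config$link,
        s_true = s_true, p_true = p_true,
        beta0 = config$beta0, beta_metric = config$beta_metric,
        beta_baseline = config$beta_baseline,
        beta_covariates = config$beta_covariates,
        sd_subject = config$sd_subject, sd_item = config$sd_item,
        sd_residual = config$sd_residual,
        lab_offsets = lab_offsets, b_subject = b_subject, b_item = b_item
      ),
      config = config
    ),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("<sim_bundle> ", x$config$n_subjects, " subjects x ",
      x$config$n_items, " items, ", x$config$n_mock_lms, " mock LMs, link ",
      if (x$config$link == "probability") "P" else
        sprintf("S^%g", x$config$k_true),
      ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
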