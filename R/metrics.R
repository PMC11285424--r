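#' Language-model scoring backends
#'
#' A `conditional_lm` wraps any autoregressive scorer behind two functions:
#' a tokenizer and a conditional next-token log-probability. Everything the
#' package computes from a language model flows through this interface, so
#' pretrained backends and table-driven mocks are interchangeable.
#'
#' @param id Backend identifier, used in all output tables.
#' @param tokenize Function mapping a character scalar to a character vector
#'   of tokens. Must return `character(0)` for empty input.
#' @param logprob Function `(context_tokens, token) -> log p(token | context)`
#'   in natural log; must be `<= 0` and finite for scorable tokens.
#' @param vocabulary Optional character vector of all tokens the backend can
#'   score (used to validate that conditional distributions normalize).
#'
#' @return An object of class `conditional_lm`.
#' @export
conditional_lm <- function(id, tokenize, logprob, vocabulary = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.function(tokenize), is.function(logprob))
  structure(
    list(id = id, tokenize = tokenize, logprob = logprob,
         vocabulary = vocabulary),
    class = "conditional_lm"
  )
}

#' @export
print.conditional_lm <- function(x, ...) {
  cat("<conditional_lm> ", x$id, "\n", sep = "")
  if (!is.null(x$vocabulary)) {
    cat("  vocabulary: ", length(x$vocabulary), " tokens\n", sep = "")
  }
  invisible(x)
}

#' Build a mock language model from a table of conditional distributions
#'
#' The table maps each context (tokens joined by single spaces; `""` for the
#' empty context) to a named vector of next-token probabilities. Every
#' distribution must sum to one within `1e-6`. Tokenization is by whitespace.
#'
#' @param table Named list of named numeric vectors, or path to a JSON file
#'   with that structure.
#' @param id Backend identifier.
#'
#' @return A [conditional_lm()].
#' @export
mock_lm_from_table <- function(table, id = "mock-table") {
  if (is.character(table) && length(table) == 1L) {
    table <- jsonlite::read_json(table, simplifyVector = TRUE)
    # JSON objects arrive as nested lists; each distribution must be a
    # named numeric vector
    table <- lapply(table, function(d) unlist(d))
  }
  stopifnot(is.list(table))
  if (is.null(names(table))) {
    abort("mock LM table must be a named list keyed by context")
  }
  vocab <- sort(unique(unlist(lapply(table, names))))
  for (i in seq_along(table)) {
    ctx <- names(table)[i]
    dist <- table[[i]]   # positional: "" (empty context) is a valid key
    if (is.null(names(dist)) || any(!nzchar(names(dist)))) {
      abort(paste0("distribution for context '", ctx, "' must name its tokens"))
    }
    if (any(dist < 0)) {
      abort(paste0("negative probability in context '", ctx, "'"))
    }
    total <- sum(dist)
    if (abs(total - 1) > 1e-6) {
      abort(sprintf(
        "distribution for context '%s' sums to %.8f, not 1 (tolerance 1e-6)",
        ctx, total
      ))
    }
  }
  conditional_lm(
    id = id,
    tokenize = function(text) {
      out <- strsplit(trimws(text), "\\s+")[[1]]
      out[nzchar(out)]
    },
    logprob = function(context_tokens, token) {
      key <- paste(context_tokens, collapse = " ")
      idx <- match(key, names(table))
      dist <- if (is.na(idx)) NULL else table[[idx]]
      if (is.null(dist)) {
        abort(paste0("mock LM '", id, "' has no distribution for context '",
                     key, "'"))
      }
      p <- unname(dist[token])
      if (is.na(p) || p <= 0) {
        abort(paste0("mock LM '", id, "' assigns no probability to token '",
                     token, "' after context '", key, "'"))
      }
      log(p)
    },
    vocabulary = vocab
  )
}

#' Score a critical word in context
#'
#' Computes the word's contextual probability and surprisal under an
#' autoregressive backend. Multi-token words are scored token by token, each
#' conditioned on the context plus the word's preceding tokens, and the
#' per-token surprisals are summed — equivalent to multiplying the
#' conditional probabilities.
#'
#' @param lm A [conditional_lm()].
#' @param context Character scalar; the text preceding the critical word
#'   (may be empty).
#' @param word The critical word.
#' @param log_base `"natural"` (nats, default) or `"base2"` (bits) for the
#'   reported surprisal. The probability is base-independent.
#' @param item_id Optional item identifier carried into the result.
#'
#' @return A one-row tibble of class `word_score` with columns `item_id`,
#'   `lm_id`, `probability`, `surprisal`, `token_count`, `log_base`.
#' @export
word_surprisal <- function(lm, context, word,
                           log_base = c("natural", "base2"),
                           item_id = NA_character_) {
  stopifnot(inherits(lm, "conditional_lm"))
  log_base <- match.arg(log_base)
  context_tokens <- lm$tokenize(context %||% "")
  word_tokens <- lm$tokenize(word)
  if (length(word_tokens) == 0L) {
    abort(paste0("word '", word, "' yields zero tokens under backend '",
                 lm$id, "'"))
  }
  s_nat <- 0
  for (i in seq_along(word_tokens)) {
    lp <- lm$logprob(c(context_tokens, word_tokens[seq_len(i - 1L)]),
                     word_tokens[i])
    if (!is.finite(lp) || lp > 0) {
      abort(sprintf(
        "backend '%s' returned invalid log-probability %s for token '%s'",
        lm$id, format(lp), word_tokens[i]
      ))
    }
    s_nat <- s_nat - lp
  }
  s <- if (log_base == "base2") s_nat / log(2) else s_nat
  out <- tibble::tibble(
    item_id = item_id,
    lm_id = lm$id,
    probability = exp(-s_nat),
    surprisal = s,
    token_count = length(word_tokens),
    log_base = log_base
  )
  class(out) <- c("word_score", class(out))
  out
}

#' Specify a probability metric
#'
#' The metric family under study: raw probability `p`, powered surprisal
#' `S^k`, and the exponentiated sub-logarithmic form `e^(S^0.6)`. Powered
#' surprisal with `k = 1` is plain surprisal.
#'
#' @param kind One of `"probability"`, `"powered_surprisal"`,
#'   `"exp_powered_surprisal"`.
#' @param exponent The power `k` for `powered_surprisal` (ignored for
#'   `probability`; fixed at 0.6 for `exp_powered_surprisal`).
#'
#' @return An object of class `metric_spec` with fields `kind`, `exponent`
#'   and a display `label`.
#' @export
metric_spec <- function(kind = c("probability", "powered_surprisal",
                                 "exp_powered_surprisal"),
                        exponent = 1) {
  kind <- match.arg(kind)
  if (kind == "exp_powered_surprisal") exponent <- 0.6
  if (kind == "probability") exponent <- NA_real_
  if (kind == "powered_surprisal" &&
      (!is.numeric(exponent) || !is.finite(exponent))) {
    abort("powered_surprisal requires a finite exponent")
  }
  label <- switch(kind,
    probability = "P",
    powered_surprisal = if (isTRUE(all.equal(exponent, 1))) "S" else
      sprintf("S^%g", exponent),
    exp_powered_surprisal = "e^(S^0.6)"
  )
  structure(list(kind = kind, exponent = exponent, label = label),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("<metric_spec> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Apply a metric specification to word scores
#'
#' @param score A `word_score` tibble (any number of rows) or an object with
#'   `probability` and `surprisal` columns.
#' @param spec A [metric_spec()].
#'
#' @return Numeric vector of metric values, one per row of `score`.
#' @export
apply_metric <- function(score, spec) {
  stopifnot(inherits(spec, "metric_spec"))
  p <- score$probability
  s <- score$surprisal
  if (spec$kind == "probability") return(p)
  if (spec$kind == "powered_surprisal") {
    k <- spec$exponent
    if (k <= 0 && any(s == 0)) {
      abort(sprintf(
        "surprisal 0 (probability 1) is not in the domain of S^%g", k))
    }
    return(s^k)
  }
  # exp_powered_surprisal
  if (any(s == 0)) {
    abort("surprisal 0 (probability 1) is not in the domain of e^(S^0.6)")
  }
  out <- exp(s^0.6)
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))
    ids <- if ("item_id" %in% names(score)) score$item_id[bad] else bad
    abort(paste0("e^(S^0.6) overflowed for item(s): ",
                 paste(ids, collapse = ", ")))
  }
  out
}

#' Standardize a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 — the
#' transformation applied to every numeric variable entering a regression.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("zscore needs a numeric vector of length >= 2")
  }
  if (any(!is.finite(values))) abort("zscore requires finite values")
  s <- sd(values)
  if (s == 0) abort("cannot z-score a constant vector")
  (values - mean(values)) / s
}

#' Score a stimulus set under several backends and metric specs
#'
#' Runs every stimulus through every backend, applies each metric spec, and
#' z-scores metric values within each (backend, metric) cell — the
#' within-dataset standardization used by all downstream regressions.
#'
#' @param lms List of [conditional_lm()] backends.
#' @param stimuli Data frame with columns `item_id`, `context`,
#'   `critical_word` (a `cloze` column, if present, is carried along).
#' @param specs List of [metric_spec()]s.
#' @param log_base Passed to [word_surprisal()].
#'
#' @return A long tibble with one row per (item, backend, metric):
#'   `item_id`, `lm_id`, `metric`, `probability`, `surprisal`, `value`,
#'   `z_value`.
#' @export
metric_table <- function(lms, stimuli, specs, log_base = "natural") {
  stopifnot(is.list(lms), length(lms) >= 1L,
            all(vapply(lms, inherits, logical(1), "conditional_lm")),
            is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "metric_spec")))
  req <- c("item_id", "context", "critical_word")
  missing_cols <- setdiff(req, names(stimuli))
  if (length(missing_cols) > 0L) {
    abort(paste0("stimuli lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ids <- vapply(lms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("duplicate backend ids")

  scores <- purrr::map_dfr(lms, function(lm) {
    purrr::map_dfr(seq_len(nrow(stimuli)), function(i) {
      tryCatch(
        word_surprisal(lm, stimuli$context[i], stimuli$critical_word[i],
                       log_base = log_base, item_id = stimuli$item_id[i]),
        error = function(e) {
          abort(paste0("cannot score item '", stimuli$item_id[i],
                       "' under backend '", lm$id, "': ", conditionMessage(e)))
        }
      )
    })
  })

  purrr::map_dfr(specs, function(spec) {
    scores |>
      dplyr::mutate(metric = spec$label, value = apply_metric(scores, spec)) |>
      dplyr::group_by(.data$lm_id) |>
      dplyr::mutate(z_value = zscore(.data$value)) |>
      dplyr::ungroup()
  }) |>
    dplyr::select("item_id", "lm_id", "metric", "probability", "surprisal",
                  "value", "z_value")
}
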