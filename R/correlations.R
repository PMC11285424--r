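#' Word-embedding providers
#'
#' An `embedding_provider` wraps any static word-embedding model behind a
#' single lookup function, so pretrained vectors and table-driven mocks are
#' interchangeable. Lookups must be deterministic; out-of-vocabulary words
#' return `NULL`.
#'
#' @param id Provider identifier.
#' @param dimension Embedding dimension (>= 2).
#' @param vector Function mapping a word to a numeric vector of that
#'   dimension, or `NULL` when the word is out of vocabulary.
#'
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(id, dimension, vector) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(dimension), dimension >= 2, is.function(vector))
  structure(list(id = id, dimension = as.integer(dimension), vector = vector),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$id, " (", x$dimension, "-d)\n", sep = "")
  invisible(x)
}

#' Build a mock embedding provider from a word-vector table
#'
#' @param table Named list of numeric vectors (all the same length >= 2),
#'   or path to a JSON file `{word: [v1, v2, ...], ...}`.
#' @param id Provider identifier.
#'
#' @return An [embedding_provider()].
#' @export
mock_embeddings <- function(table, id = "mock-embeddings") {
  if (is.character(table) && length(table) == 1L) {
    table <- jsonlite::read_json(table, simplifyVector = TRUE)
  }
  stopifnot(is.list(table), !is.null(names(table)))
  dims <- unique(lengths(table))
  if (length(dims) != 1L || dims < 2L) {
    abort("all embedding vectors must share one dimension >= 2")
  }
  norms <- vapply(table, function(v) sqrt(sum(as.numeric(v)^2)), numeric(1))
  if (any(norms == 0)) {
    abort(paste0("zero vector for word(s): ",
                 paste(names(table)[norms == 0], collapse = ", ")))
  }
  embedding_provider(
    id = id, dimension = dims,
    vector = function(word) {
      v <- table[[word]]
      if (is.null(v)) NULL else as.numeric(v)
    }
  )
}

#' Cosine similarity between a critical word and its context
#'
#' The contextual-similarity proxy for semantic feature overlap: the cosine
#' of the angle between the critical word's embedding and the unweighted
#' mean of the embeddings of the context words. Context words the provider
#' cannot embed are skipped and counted.
#'
#' @param provider An [embedding_provider()].
#' @param context_words Character vector of context words (words preceding
#'   the critical word).
#' @param critical_word The critical word.
#'
#' @return Numeric scalar in `[-1, 1]`, with attribute `n_skipped` giving
#'   the number of unembeddable context words.
#' @export
contextual_similarity <- function(provider, context_words, critical_word) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (length(context_words) < 1L) abort("no context words supplied")
  vecs <- lapply(context_words, provider$vector)
  skipped <- vapply(vecs, is.null, logical(1))
  if (all(skipped)) abort("no embeddable context words")
  crit <- provider$vector(critical_word)
  if (is.null(crit)) {
    abort(paste0("critical word '", critical_word, "' is out of vocabulary"))
  }
  ctx_mean <- Reduce(`+`, vecs[!skipped]) / sum(!skipped)
  nc <- sqrt(sum(ctx_mean^2)); nw <- sqrt(sum(crit^2))
  if (nc == 0 || nw == 0) {
    abort("degenerate similarity: zero-norm context mean or critical vector")
  }
  out <- sum(ctx_mean * crit) / (nc * nw)
  attr(out, "n_skipped") <- sum(skipped)
  out
}

#' Split a stimulus context into embeddable words
#'
#' Lowercases, strips punctuation, and splits on whitespace — the
#' convention used when computing contextual similarity from raw stimulus
#' text.
#'
#' @param context Character scalar.
#' @return Character vector of words (possibly empty).
#' @export
context_words <- function(context) {
  cleaned <- tolower(gsub("[^[:alnum:][:space:]'-]", " ", context %||% ""))
  out <- strsplit(trimws(cleaned), "\\s+")[[1]]
  # keep intra-word apostrophes/hyphens but drop bare punctuation tokens
  out[grepl("[[:alnum:]]", out)]
}

cor_row <- function(x, y, metric, target, lm_id, dataset) {
  if (length(x) < 3L) {
    abort(paste0("fewer than 3 usable items for ", metric, " vs ", target))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort(paste0("zero variance in ", metric, " or ", target,
                 " among usable items"))
  }
  tibble::tibble(
    dataset = dataset, lm_id = lm_id, metric = metric, target = target,
    abs_r = abs(cor(x, y)), n_used = length(x)
  )
}

#' Correlate a metric with cloze probability
#'
#' Computes |Pearson r| between a model-derived metric and cloze
#' probability, restricted to items whose cloze is strictly greater than
#' the threshold (default 0.05) — the range over which cloze is considered
#' a meaningful estimate of subjective predictability.
#'
#' @param items Data frame with a `cloze` column and the metric column.
#' @param metric Name of the metric column in `items`.
#' @param filter_threshold Keep items with `cloze > filter_threshold`.
#' @param lm_id,dataset Labels carried into the result.
#'
#' @return One-row tibble: `dataset`, `lm_id`, `metric`, `target`
#'   (`"cloze"`), `abs_r`, `n_used`.
#' @export
correlate_with_cloze <- function(items, metric, filter_threshold = 0.05,
                                 lm_id = NA_character_,
                                 dataset = NA_character_) {
  stopifnot(is.data.frame(items), "cloze" %in% names(items),
            metric %in% names(items))
  keep <- is.finite(items$cloze) & is.finite(items[[metric]]) &
    items$cloze > filter_threshold
  cor_row(items[[metric]][keep], items$cloze[keep],
          metric = metric, target = "cloze", lm_id = lm_id, dataset = dataset)
}

#' Correlate a metric with contextual similarity
#'
#' |Pearson r| between a model-derived metric and embedding-based
#' contextual similarity, over all items (no cloze filter applies here).
#'
#' @param items Data frame holding the metric column and a `similarity`
#'   column (or pass `similarities`).
#' @param metric Name of the metric column.
#' @param similarities Optional numeric vector overriding
#'   `items$similarity`.
#' @param lm_id,dataset Labels carried into the result.
#'
#' @return One-row tibble as in [correlate_with_cloze()], with `target`
#'   `"contextual_similarity"`.
#' @export
correlate_with_similarity <- function(items, metric, similarities = NULL,
                                      lm_id = NA_character_,
                                      dataset = NA_character_) {
  stopifnot(is.data.frame(items), metric %in% names(items))
  sim <- similarities %||% items$similarity
  if (is.null(sim)) abort("no similarity values supplied")
  stopifnot(length(sim) == nrow(items))
  keep <- is.finite(sim) & is.finite(items[[metric]])
  cor_row(items[[metric]][keep], sim[keep], metric = metric,
          target = "contextual_similarity", lm_id = lm_id, dataset = dataset)
}

#' Correlation between cloze probability and contextual similarity
#'
#' @param items Data frame with `cloze` and `similarity` columns.
#' @param dataset Label carried into the result.
#'
#' @return One-row tibble with `metric = "cloze"`,
#'   `target = "contextual_similarity"`, `abs_r`, `n_used`.
#' @export
cloze_similarity_correlation <- function(items, dataset = NA_character_) {
  stopifnot(is.data.frame(items),
            all(c("cloze", "similarity") %in% names(items)))
  keep <- is.finite(items$cloze) & is.finite(items$similarity)
  cor_row(items$cloze[keep], items$similarity[keep], metric = "cloze",
          target = "contextual_similarity", lm_id = NA_character_,
          dataset = dataset)
}
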