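test_that("word_surprisal matches hand-computed single- and multi-token cases", {
  lm1 <- mock_lm_from_table(unit_surprisal_table, id = "unit")
  s1 <- word_surprisal(lm1, "", "w")
  expect_equal(s1$surprisal, 1, tolerance = 1e-12)
  expect_equal(s1$probability, exp(-1), tolerance = 1e-12)
  expect_equal(s1$token_count, 1L)

  lm2 <- mock_lm_from_table(two_token_table, id = "two")
  s2 <- word_surprisal(lm2, "", "a b")
  expect_equal(s2$probability, 0.1, tolerance = 1e-12)
  expect_equal(s2$surprisal, -log(0.1), tolerance = 1e-12)
  expect_equal(s2$token_count, 2L)

  # base-2 reporting: same probability, rescaled surprisal
  s2b <- word_surprisal(lm2, "", "a b", log_base = "base2")
  expect_equal(s2b$surprisal, -log2(0.1), tolerance = 1e-12)
  expect_equal(s2b$probability, 0.1, tolerance = 1e-12)
})

test_that("word_surprisal agrees with a count-based bigram oracle", {
  lm <- bigram_lm()
  cases <- list(
    list(context = "", word = "the"),
    list(context = "the", word = "cat"),
    list(context = "the cat", word = "sat on"),
    list(context = "a", word = "dog saw a cat")
  )
  for (cs in cases) {
    got <- word_surprisal(lm, cs$context, cs$word)
    want <- bigram_surprisal_oracle(cs$context, cs$word)
    expect_equal(got$surprisal, want, tolerance = 1e-12)
    expect_equal(got$probability, exp(-want), tolerance = 1e-12)
  }
})

test_that("scoring is deterministic and rejects contract violations", {
  lm <- bigram_lm()
  a <- word_surprisal(lm, "the", "cat")
  b <- word_surprisal(lm, "the", "cat")
  expect_identical(a$surprisal, b$surprisal)

  expect_error(word_surprisal(lm, "the", "   "), "zero tokens")

  bad <- conditional_lm("bad", tokenize = function(x) "t",
                        logprob = function(ctx, tok) 0.1)
  expect_error(word_surprisal(bad, "", "t"), "invalid log-probability")
  bad2 <- conditional_lm("bad2", tokenize = function(x) "t",
                         logprob = function(ctx, tok) NaN)
  expect_error(word_surprisal(bad2, "", "t"), "invalid log-probability")
})

test_that("mock LM tables validate their distributions", {
  expect_silent(mock_lm_from_table(setNames(list(c(a = 0.5, b = 0.5)), "")))
  expect_error(mock_lm_from_table(setNames(list(c(a = 0.5, b = 0.4)), "")),
               "sums to")
  expect_error(mock_lm_from_table(setNames(list(c(a = -0.1, b = 1.1)), "")),
               "negative")
  # full-vocabulary normalization of every context in the toy tables
  for (tbl in list(two_token_table, unit_surprisal_table)) {
    for (i in seq_along(tbl)) expect_lt(abs(sum(tbl[[i]]) - 1), 1e-6)
  }
})

test_that("apply_metric computes the metric family", {
  sc <- tibble::tibble(probability = exp(-c(4, 2, 8)),
                       surprisal = c(4, 2, 8), item_id = c("a", "b", "c"))
  expect_equal(apply_metric(sc, metric_spec("powered_surprisal", 0.5))[1], 2)
  expect_equal(apply_metric(sc, metric_spec("powered_surprisal", -1))[2], 0.5)
  expect_equal(apply_metric(sc, metric_spec("probability")),
               exp(-c(4, 2, 8)))
  # high-precision route for e^(S^0.6): 8^0.6 = e^(0.6 ln 8)
  expect_equal(apply_metric(sc, metric_spec("exp_powered_surprisal"))[3],
               exp(exp(0.6 * log(8))), tolerance = 1e-12)
  # k = 1 reproduces surprisal exactly
  expect_identical(apply_metric(sc, metric_spec("powered_surprisal", 1)),
                   sc$surprisal)
})

test_that("apply_metric rejects degenerate and overflowing inputs", {
  sc0 <- tibble::tibble(probability = 1, surprisal = 0, item_id = "z")
  expect_error(apply_metric(sc0, metric_spec("powered_surprisal", -1)),
               "domain")
  expect_error(apply_metric(sc0, metric_spec("exp_powered_surprisal")),
               "domain")
  big <- tibble::tibble(probability = 0, surprisal = 1e6, item_id = "huge")
  expect_error(apply_metric(big, metric_spec("exp_powered_surprisal")),
               "huge")
})

test_that("zscore standardizes, is idempotent and affine-invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  set.seed(42)
  x <- rnorm(50)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(zscore(z), z, tolerance = 1e-10)
  expect_equal(zscore(3 + 2.5 * x), z, tolerance = 1e-10)
  expect_true(all(order(z) == order(x)))
  expect_error(zscore(rep(1, 5)), "constant")
  expect_error(zscore(1), "length")
})

test_that("metric_table has one row per (item, lm, spec) and is self-consistent", {
  stimuli <- tibble::tibble(
    item_id = c("i1", "i2", "i3"),
    context = c("", "the", "the cat"),
    critical_word = c("the", "cat", "sat")
  )
  lms <- list(bigram_lm(),
              conditional_lm("toy-bigram-copy", bigram_lm()$tokenize,
                             bigram_lm()$logprob))
  specs <- list(metric_spec("probability"),
                metric_spec("powered_surprisal", 1),
                metric_spec("powered_surprisal", 0.6))
  tbl <- metric_table(lms, stimuli, specs)
  expect_equal(nrow(tbl), 3 * 2 * 3)
  # identical backends give identical metric columns
  a <- tbl[tbl$lm_id == "toy-bigram", ]
  b <- tbl[tbl$lm_id == "toy-bigram-copy", ]
  expect_equal(a$value, b$value)
  # surprisal column is -log of probability column
  expect_equal(tbl$surprisal, -log(tbl$probability), tolerance = 1e-12)
  # z-scoring is within (lm, spec)
  zs <- dplyr::summarise(dplyr::group_by(tbl, lm_id, metric),
                         m = mean(z_value), s = sd(z_value))
  expect_true(all(abs(zs$m) < 1e-10))
  expect_true(all(abs(zs$s - 1) < 1e-10))

  expect_error(metric_table(list(bigram_lm(), bigram_lm()), stimuli, specs),
               "duplicate")
  bad_stim <- dplyr::mutate(stimuli,
                            critical_word = c("the", "cat", "zebra"))
  expect_error(metric_table(lms, bad_stim, specs), "i3")
})

test_that("multi-token surprisal equals -log of the probability product", {
  set.seed(11)
  for (rep in 1:20) {
    n_tok <- sample(1:4, 1)
    probs <- runif(n_tok, 0.05, 0.95)
    tbl <- list()
    ctx <- character(0)
    for (j in seq_len(n_tok)) {
      tok <- paste0("t", j)
      dist <- setNames(c(probs[j], 1 - probs[j]), c(tok, "zzz"))
      tbl[[paste(ctx, collapse = " ")]] <- dist
      ctx <- c(ctx, tok)
    }
    tbl[[paste(ctx, collapse = " ")]] <- c(zzz = 1)
    lm <- mock_lm_from_table(tbl, id = "rand")
    sc <- word_surprisal(lm, "", paste0("t", seq_len(n_tok), collapse = " "))
    expect_equal(sc$surprisal, -log(prod(probs)), tolerance = 1e-12)
    expect_equal(sc$token_count, n_tok)
  }
})

test_that("S^k is monotone in S with the sign of k", {
  s <- sort(runif(25, 0.01, 15))
  sc <- tibble::tibble(probability = exp(-s), surprisal = s)
  for (k in c(0.3, 1, 2)) {
    v <- apply_metric(sc, metric_spec("powered_surprisal", k))
    expect_true(all(diff(v) > 0))
  }
  for (k in c(-0.5, -1)) {
    v <- apply_metric(sc, metric_spec("powered_surprisal", k))
    expect_true(all(diff(v) < 0))
  }
})

test_that("z-scored S^k is log-base invariant but e^(S^0.6) is not", {
  set.seed(3)
  s_nat <- runif(30, 0.5, 10)
  sc_nat <- tibble::tibble(probability = exp(-s_nat), surprisal = s_nat)
  sc_bit <- tibble::tibble(probability = exp(-s_nat),
                           surprisal = s_nat / log(2))
  for (k in c(0.4, 0.6, 1, 2)) {
    spec <- metric_spec("powered_surprisal", k)
    expect_equal(zscore(apply_metric(sc_nat, spec)),
                 zscore(apply_metric(sc_bit, spec)), tolerance = 1e-10)
  }
  spec_e <- metric_spec("exp_powered_surprisal")
  z_nat <- zscore(apply_metric(sc_nat, spec_e))
  z_bit <- zscore(apply_metric(sc_bit, spec_e))
  expect_gt(max(abs(z_nat - z_bit)), 1e-3)
})

test_that("shipped example backends load from JSON", {
  lm_path <- system.file("extdata", "example_mock_lm.json",
                         package = "n400link")
  lm <- mock_lm_from_table(lm_path, id = "example")
  sc <- word_surprisal(lm, "the", "dogs run")
  expect_equal(sc$probability, 0.6 * 1.0, tolerance = 1e-12)

  emb_path <- system.file("extdata", "example_embeddings.json",
                          package = "n400link")
  emb <- mock_embeddings(emb_path)
  got <- contextual_similarity(emb, c("the", "dogs"), "cats")
  expect_gt(as.numeric(got), 0.8)
})
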