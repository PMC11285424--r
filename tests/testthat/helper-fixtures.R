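# Shared in-code fixtures for the test suite.

# two-token mock: "ab" tokenizes to "a" "b"; p(a|"") = 0.2, p(b|a) = 0.5
two_token_table <- setNames(
  list(c(a = 0.2, x = 0.8), c(b = 0.5, x = 0.5), c(x = 1)),
  c("", "a", "a b")
)

# single-token mock with p(w) = exp(-1)
unit_surprisal_table <- setNames(
  list(setNames(c(exp(-1), 1 - exp(-1)), c("w", "other"))),
  ""
)

# small trial table written to a temp file for I/O tests
write_trial_fixture <- function(path, n_missing_amplitude = 0) {
  df <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 5),
    item_id = rep(sprintf("i%d", 1:5), 2),
    lab = rep(c("labA", "labB"), each = 5),
    amplitude = round(seq(-2, 2, length.out = 10), 3),
    baseline = round(seq(0.5, 1.4, by = 0.1), 3),
    concreteness = round(seq(1, 10), 3),
    log_frequency = round(log(1:10), 3),
    old20 = round(seq(1.1, 2, by = 0.1), 3),
    sentence_position = rep(3:7, 2)
  )
  if (n_missing_amplitude > 0) {
    df$amplitude[seq_len(n_missing_amplitude)] <- NA
  }
  utils::write.csv(df, path, row.names = FALSE)
  df
}

# balanced random-intercept simulation used by the mixed-model tests
sim_random_intercept <- function(n_subjects, n_per_subject, beta = c(1, 0.5),
                                 sd_subject = 0.8, sd_resid = 1, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_subjects), each = n_per_subject)
  x <- rnorm(n_subjects * n_per_subject)
  y <- beta[1] + beta[2] * x + rnorm(n_subjects, 0, sd_subject)[g] +
    rnorm(length(g), 0, sd_resid)
  data.frame(response = y, x = x, subject_id = factor(g))
}
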