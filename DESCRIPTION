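Package: n400link
Title: Estimating the Functional Link Between Word Probability and N400 Amplitude
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for determining the mathematical form of the relationship
    between a word's contextual probability under an autoregressive language
    model and the amplitude of the N400 event-related potential. Computes
    word-level probability, surprisal and power-transformed surprisal metrics
    from pluggable language-model scoring backends, fits trial-level linear
    mixed-effects regressions of single-trial N400 amplitude on each metric,
    estimates the best-fitting surprisal exponent by smoothing AIC over an
    exponent grid with per-model random offsets, runs a likelihood-ratio
    variance-partitioning battery with Benjamini-Yekutieli false discovery
    rate control, and correlates metrics with cloze probability and
    embedding-based contextual similarity. A synthetic-data generator with
    known ground truth makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
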