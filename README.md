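# n400link

**What is the mathematical form of the link between a word's contextual
probability and N400 amplitude?**

The N400 is an event-related brain potential whose amplitude tracks how
hard a word is to integrate with its context. Two classic proposals link
it to the word's contextual probability $p$: a *linear* effect of $p$
itself, or a *logarithmic* effect — a linear effect of surprisal
$S = -\log p$. `n400link` implements the analysis machinery for asking
whether the truth lies in between: it fits trial-level linear
mixed-effects regressions of single-trial N400 amplitude on the metric
family

$$p, \qquad S^k \ (k \in [0.1, 2]), \qquad e^{S^{0.6}},$$

with probabilities supplied by any autoregressive language-model scoring
backend, and estimates the best-fitting exponent $\hat k$ by smoothing the
regression-AIC surface over the exponent grid across language models
(a penalized thin-plate spline with per-model random offsets, evaluated
for a dummy model). $\hat k < 1$ is a *sub-logarithmic* link. Around this
core it provides:

* the two standard regression recipes for trial-level N400 data
  (multi-lab: baselined amplitude, lab fixed effect, subject intercepts;
  single-lab: raw amplitude, baseline + lexical covariates, baseline
  slopes by subject and item),
* a maximum-likelihood mixed-model engine (AIC, likelihood-ratio tests,
  Benjamini–Yekutieli FDR across the whole family of tests in a run),
* the eight-test variance-partitioning battery asking whether $P$, $S$ or
  $S^{0.6}$ explains amplitude variance beyond the others,
* correlations of every metric with cloze probability (items with
  cloze > 0.05) and with embedding-based contextual similarity,
* a synthetic-data generator with known ground truth — trial tables, mock
  language models, cloze norms, mock embeddings — so the entire pipeline
  is testable end to end without any external data or pretrained models.

The package is tidyverse-native: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

It is aimed at researchers in computational psycholinguistics and
cognitive neuroscience who work with single-trial ERP regression designs
and language-model predictability metrics.

## Worked example

Simulate a study whose amplitudes are generated from an $S^{0.6}$ link,
then recover the exponent, contrast the metrics, and correlate them with
cloze:

```r
library(n400link)
library(dplyr)

bundle <- simulate_n400(sim_config(k_true = 0.6, seed = 42))
bundle
#> <sim_bundle> 30 subjects x 60 items, 5 mock LMs, link S^0.6, seed 42

a1 <- run_analysis1(bundle$dataset, bundle$scores)
glance(a1$estimate)
#> # A tibble: 1 × 5
#>   k_hat boundary fit_quality pooled n_lms
#>   <dbl> <lgl>          <dbl> <lgl>  <int>
#> 1   0.6 FALSE          0.998 FALSE      5
```

The smoothed AIC surface over 5 mock language models bottoms out at
$\hat k = 0.6$ — the generating exponent — and the smoother tracks the
surface almost perfectly (adjusted $R^2 = 0.998$).

```r
a23 <- run_analysis2_3(bundle$dataset, bundle$scores)
as_tibble(a23$contrasts) |> select(contrast, delta_aic, substantial, p_adjusted)
#> # A tibble: 3 × 4
#>   contrast delta_aic substantial p_adjusted
#>   <chr>        <dbl> <lgl>            <dbl>
#> 1 P-S          657.  TRUE          6.13e-14
#> 2 P-S^0.6      707.  TRUE          2.69e-14
#> 3 S-S^0.6       50.4 TRUE          4.39e- 9
```

Each `delta_aic` is the estimated AIC difference across language models
(positive = the second metric fits better): surprisal beats probability by
~657 AIC units, and $S^{0.6}$ beats plain surprisal by ~50 — far past the
conventional "substantial" threshold of 4.

```r
run_analysis4(bundle$stimuli, bundle$scores, bundle$embeddings, "synthetic") |>
  filter(target == "cloze") |>
  group_by(metric) |> summarise(mean_abs_r = mean(abs_r)) |>
  arrange(desc(mean_abs_r))
#> # A tibble: 4 × 2
#>   metric    mean_abs_r
#>   <chr>          <dbl>
#> 1 S^0.6          0.892
#> 2 S              0.879
#> 3 e^(S^0.6)      0.784
#> 4 P              0.697
```

$S^{0.6}$ correlates most strongly with cloze probability, as designed
into the generator (cloze is a noisy monotone function of $S^{0.6}$).

Real data enter through `load_trials()` (CSV/TSV with a column-mapping
schema), `metric_table()` with any `conditional_lm` backend (a JSON
table-driven mock is built in; pretrained scorers plug in through the same
two-function contract), and `mock_embeddings()`/`embedding_provider` for
similarity.

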