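---
title: "Models and methods behind n400link"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind n400link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n400link)
```

## The scientific question

The N400 is a negative-going event-related potential peaking around 400 ms
after a word is presented; its amplitude indexes how hard the word is to
process semantically, and it shrinks when the word is supported by its
context. A long-standing question is the *functional form* linking a word's
contextual probability $p$ to N400 amplitude: is the effect linear in $p$,
linear in surprisal $S = -\log p$ (a logarithmic link), or something in
between? `n400link` implements the analysis machinery for answering this
with autoregressive language models as the probability source: the family
of candidate metrics $p$, $S^k$, and $e^{S^{0.6}}$; trial-level
mixed-effects regressions of single-trial amplitude on each metric; AIC
surfaces over a grid of exponents $k$ smoothed across language models to
estimate the best-fitting exponent $\hat k$; a likelihood-ratio
variance-partitioning battery; and correlations of each metric with cloze
probability and embedding-based contextual similarity. A value $\hat k < 1$
indicates a *sub-logarithmic* link — steeper than surprisal at the
high-probability end, shallower at the low end.

Everything is testable without external data: a synthetic-data generator
produces trial tables, mock language models, cloze norms and mock
embeddings from a known generating model, so ground truth is available for
every stage.

## Word-level metrics

A scoring backend (`conditional_lm`) exposes a tokenizer and a conditional
next-token log-probability. Multi-token critical words are scored token by
token, each conditioned on the context plus the word's earlier tokens, and
per-token surprisals are summed — equivalent to multiplying conditional
probabilities. `word_surprisal()` enforces the backend contract
(log-probabilities finite and non-positive) and records the token count.

Surprisal is reported in nats by default, with bits selectable. Because all
regressions standardize their predictors, the base cancels for $p$, $S$ and
$S^k$ (asserted in the tests via $(cS)^k = c^k S^k$); it does *not* cancel
for $e^{S^{0.6}}$, so the base is carried in every output. Words with
$p = 1$ (zero surprisal) raise an error for metrics with $k \le 0$ and for
$e^{S^{0.6}}$ rather than being clipped: genuinely degenerate stimuli
should surface, and softmax-based backends cannot produce them.

## Regression recipes and the mixed-model engine

Two preset recipes cover the two dataset traditions:

* `lab_random_subject`: baselined amplitude ~ metric + lab, random
  intercept per subject. Multi-lab data; no item terms.
* `baseline_covariates`: raw amplitude ~ baseline + concreteness +
  log frequency + OLD20 + sentence position + metric, random baseline
  slopes for subject and item plus an item intercept. The wording of the
  structure leaves open whether the subject term also has an intercept; we
  default to slope + intercept (the maximal structure consistent with the
  stated slopes) and expose `subject_intercept = FALSE` for the slope-only
  reading.

Every numeric variable entering a design is z-scored, including (by
default) the dependent variable; AIC *differences* between metrics are
invariant to this common affine transform (asserted in the tests), and
`scale_dv = FALSE` is available when raw-scale variance components are the
quantity of interest.

All models are fitted by **maximum likelihood**, not REML: the package's
inferential currency is AIC comparison and likelihood-ratio tests across
models differing in fixed effects, which are only valid under ML. The
parameter count for AIC is fixed coefficients + distinct
variance/covariance parameters + residual variance. Optimizer settings are
frozen (bobyqa, derivative checks off) so fits are deterministic; singular
fits are flagged, never silently rejected, since the recipes were chosen
to avoid them at realistic sizes. The engine is validated against an
independent brute-force optimizer of the closed-form marginal Gaussian
likelihood on random-intercept problems (agreement to $10^{-4}$ in
deviance).

The eight-test battery (`variance_partition()`) asks whether each of $P$,
$S$, $S^{0.6}$ explains variance beyond the others: `S^0.6 + S`,
`S^0.6 + P`, `S + S^0.6`, `S + P`, `P + S`, `P + S^0.6` and
`(S + P) + S^0.6` with 1 df, and `S^0.6 + (S + P)` with 2 df (labels read
"base + added"; the df follow the printed convention of the battery).
P-values are corrected by the Benjamini–Yekutieli step-up rule, valid
under arbitrary dependence. The battery should be run under a recipe with
item random effects (the single-lab covariate recipe): the metrics are
item-level predictors, and with item-level noise present a
subject-intercept-only model pseudoreplicates them, inflating the type-I
rate of the null tests well past nominal; when the battery is run inside
`run_analysis2_3()` a *single* family covers every p-value of the run, and
the family membership is written alongside the results so alternative
groupings can be audited.

## Estimating the exponent

`sweep_exponents()` fits the dataset's recipe with $z(S^k)$ as the metric
for every backend and every $k$ on the grid — all 0.1 steps in $[0.1, 2]$
plus $-1, -0.5, -0.1$ for comparison. Negative exponents feed the surface
and plots only; the estimation grid is $k \in \{0, 0.1, \dots, 2\}$.
`estimate_k()` smooths the surface with a generalized additive model,

$$\mathrm{AIC} \sim s(k) + s(\mathrm{lm}, \mathrm{bs} = \texttt{"re"}),$$

a thin-plate penalized spline in $k$ (basis dimension 10, wiggliness by
REML marginal likelihood) with a Gaussian random offset per language
model, then predicts the population-level curve for a dummy, non-existent
language model (random offsets excluded from the prediction) and takes the
grid minimizer. Estimates on the boundary of $[0, 2]$ are flagged. The
smoother's adjusted $R^2$ is reported as `fit_quality` because the
analysis is only meaningful when the spline actually tracks the surface
(values above 0.9 are typical on both real and synthetic surfaces). Pooled
estimation across datasets adds a per-dataset random offset and one global
curve.

`metric_contrasts()` quantifies pairwise metric differences by a mixed
model of AIC on metric with a random intercept per language model; in a
balanced table the estimate equals the mean paired AIC difference
(asserted to $10^{-6}$). A difference of 4 or more AIC units is flagged
"substantial" by the usual convention; the comparison uses a $10^{-8}$
numerical tolerance so exact-boundary tables flag deterministically.

## Correlations with cloze and contextual similarity

Contextual similarity is the cosine between a critical word's embedding
and the unweighted mean of its context-word embeddings. Context words are
all whitespace-separated words preceding the critical word, lowercased and
with punctuation stripped; out-of-vocabulary words are skipped and
counted. Correlations with cloze use only items with cloze strictly
greater than 0.05 — the range over which cloze plausibly measures
subjective predictability — and require at least three surviving items;
correlations with similarity use all items. Only $|r|$ is reported, since
metric orientations differ ($p$ decreasing in surprisal, $S^k$
increasing).

## The synthetic generator

`simulate_n400()` draws one complete study:

$$y_{ij} = \beta_0 + \beta_m\, z(\ell(p_i)) + \beta_b\, z(b_{ij}) +
\textstyle\sum_c \beta_c\, z(x_{ci}) + \lambda_{g(j)} + u_j + v_i +
\varepsilon_{ij}$$

with link $\ell(p) = S^{k_{\mathrm{true}}}$ (or $p$), item surprisal
log-uniform on $[0.5, 12]$ nats, standard-normal baselines and covariates,
round-robin lab assignment with small additive lab offsets, and Gaussian
subject/item/residual noise. Standardization happens on the expanded trial
vectors — exactly the columns the fitted regressions standardize — so with
all noise at zero the generating coefficients are recovered to machine
precision. Each mock language model observes the item log-probability plus
Gaussian noise (clipped to a minimum surprisal of 0.01 nats so
probabilities stay in $(0,1)$); cloze is a noisy decreasing function of
$z(S^{0.6})$ clamped to $[0,1]$; embeddings are constructed geometrically
so each item's contextual similarity is *exact* by construction and
correlates with true surprisal at a configurable target (default $-0.5$).

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| subjects × items | 30 × 60 | mid-sized ERP study; 1800 trials |
| labs | 3 | smallest multi-lab design with an estimable lab effect |
| mock LMs | 5 | enough for the per-LM random offset to be identified |
| $\beta_m$ | $-1$ | more surprising words → more negative amplitude |
| $\beta_b$, $\beta_c$ | 0.25, 0.05 | baseline dominates other nuisance covariates |
| $\sigma_\mathrm{subject}, \sigma_\mathrm{item}, \sigma_\mathrm{resid}$ | 0.5, 0.1, 0.75 | subject variance largest, per ERP convention |
| LM noise | 0.1 nats | see below |
| surprisal range | 0.5–12 nats | spans high-cloze to very unexpected words |

The noise defaults were fixed by an explicit identifiability analysis
before the validation suite was written. Two constraints bind. First, the
exponent grid has 0.1 resolution, and adjacent transforms $S^k$,
$S^{k+0.1}$ correlate above 0.999 on this surprisal distribution, so
item-level variance the recipe cannot absorb (item effects, unmodeled
covariate signal, residual noise averaged over 30 subjects) directly blurs
the AIC profile in $k$; the defaults keep that blur below one grid step.
Second, language-model observation noise acts as error-in-variables on a
*nonlinearly transformed* regressor: a population-level computation shows
that with noise of 0.25 nats on surprisal the best-correlating exponent
for a generating $S^{0.4}$ link is $0.5$ — a full grid step of bias —
whereas at 0.1 nats the argmax is unbiased on the grid over
$k_\mathrm{true} \in \{0.4, 0.6, 1.0\}$. The default of 0.1 nats therefore
makes $k_\mathrm{true}$ the estimand, which is what a validation study
needs. It is deliberately *less* inter-model disagreement than real
language models exhibit: with realistic disagreement the recovered
exponent is a noise-shifted version of the generating one, which is worth
remembering when interpreting exponent estimates from any single family of
models.

### What passing tests do and do not show

The generator emulates the *statistical structure* of trial-level N400
regressions: crossed subject/item effects, lab structure, covariates, a
known metric link, noisy LM observations of a common truth. It does not
emulate EEG waveforms, electrode topography, artifact structure,
non-Gaussian single-trial noise, serial dependence within a session, or
the lexical correlation structure of real stimuli (where frequency,
concreteness and predictability co-vary). Recovery results on synthetic
data therefore validate the *pipeline* — that the estimator finds the
generating link when one exists — not the empirical claim that any
particular $k$ characterizes human data.

## Numerical choices and degenerate inputs

Fits are deterministic given the data (fixed optimizer, no randomness);
the battery refits each distinct fixed-term set once and reuses it across
tests. LRT statistics are clipped at zero, with a warning past a $10^{-6}$
tolerance (an augmented model can only lose to its base model through
optimizer failure). Constant vectors cannot be z-scored; single-level
grouping factors, rank-deficient fixed designs, collinear metric triples,
zero-norm embedding means, all-equal AIC surfaces and sub-3-item
correlation sets all raise immediate, named errors rather than propagating
NaNs. Exponent estimates never extrapolate beyond $[0, 2]$.

## Problem sizes used in the validation suite

The shipped tests run the full pipeline at the generator defaults
(30 × 60, 5 mock LMs, 23-point grid: about 115 mixed-model fits per
bundle) over 20 seeds per generating exponent in $\{0.4, 0.6, 1.0\}$; the
variance-partition calibration uses 50 seeds; LRT null calibration uses
2000 replicates of a 12-subject × 8-trial design; the engine-vs-oracle
check uses 30 random-intercept problems of at most 200 rows. These sizes
were chosen to give stable rates while keeping a full suite run in the
tens of minutes on a single core.

## Known limitations

* The exponent estimator inherits the 0.1-step grid and never
  interpolates between grid points. Recovery is hardest near $k = 1$,
  where adjacent powered transforms are most collinear and the AIC profile
  is flattest: at the default design size the estimator's sampling
  deviation there is about one grid step.
* Only Gaussian linear mixed models are supported; no GLMMs, no Bayesian
  fits.
* Random slopes for the metric itself are not offered (they are known to
  produce singular fits at these sizes, and AIC comparability requires a
  common random structure across metrics).
* Masked/bidirectional language models are out of scope: the multi-token
  product rule requires autoregressive factorization.
* With realistic language-model disagreement, errors-in-variables bias
  means the best-fitting exponent for *observed* metrics can differ from
  the generating exponent by about one grid step at the low end.
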