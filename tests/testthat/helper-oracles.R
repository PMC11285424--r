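# Independent oracles: each reimplements a quantity from first principles,
# sharing no code with the package paths it checks.

# Benjamini-Yekutieli step-up, straight from the definition:
# adj_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j), c(m) = sum 1/i.
by_step_up_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  raw <- pmin(1, ps * m * cm / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force maximum of the marginal Gaussian likelihood for a
# random-intercept model y = X beta + Z b + e, b ~ N(0, sb^2), e ~ N(0, se^2):
# beta is profiled by GLS at each (sb, se); (sb, se) maximized numerically
# from several starts. Returns the maximized log-likelihood.
profiled_ml_oracle <- function(y, X, group) {
  n <- length(y)
  Z <- model.matrix(~ 0 + factor(group))
  negll <- function(theta) {
    sb <- exp(theta[1]); se <- exp(theta[2])
    V <- sb^2 * tcrossprod(Z) + diag(se^2, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (n * log(2 * pi) + logdet + sum(r * Vi_r))
  }
  starts <- list(c(0, 0), c(-2, 0), c(0, -2), c(-4, -1), c(1, 1))
  best <- Inf
  for (s in starts) {
    fit <- optim(s, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    fit <- optim(fit$par, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  -best
}

# Count-based bigram model over a tiny corpus, plus a direct hand oracle for
# the surprisal of a word: -log of the product of bigram relative
# frequencies. "<s>" marks sentence starts.
toy_corpus <- c(
  "the cat sat on the mat",
  "the dog sat on the rug",
  "the cat saw the dog",
  "a dog saw a cat",
  "the mat was red",
  "a cat sat on a rug"
)

bigram_counts <- local({
  counts <- list()
  for (sent in toy_corpus) {
    toks <- c("<s>", strsplit(sent, " ")[[1]])
    for (i in seq_len(length(toks) - 1L)) {
      key <- toks[i]
      counts[[key]] <- c(counts[[key]], toks[i + 1L])
    }
  }
  lapply(counts, table)
})

bigram_prob <- function(prev, word) {
  tab <- bigram_counts[[prev]]
  n <- tab[word]
  if (is.na(n)) stop("unseen bigram: ", prev, " -> ", word)
  as.numeric(n) / sum(tab)
}

# conditional_lm backend over the same counts (package-facing route)
bigram_lm <- function() {
  conditional_lm(
    id = "toy-bigram",
    tokenize = function(text) {
      out <- strsplit(trimws(text), "\\s+")[[1]]
      out[nzchar(out)]
    },
    logprob = function(context_tokens, token) {
      prev <- if (length(context_tokens) == 0L) "<s>" else
        context_tokens[length(context_tokens)]
      log(bigram_prob(prev, token))
    }
  )
}

# hand route: surprisal of a multi-word string after a context, by direct
# bigram product
bigram_surprisal_oracle <- function(context, words) {
  toks <- c("<s>", strsplit(trimws(context), "\\s+")[[1]])
  toks <- toks[nzchar(toks)]
  total <- 0
  prev <- toks[length(toks)]
  for (w in strsplit(words, "\\s+")[[1]]) {
    total <- total - log(bigram_prob(prev, w))
    prev <- w
  }
  total
}
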