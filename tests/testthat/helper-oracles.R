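# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive re-derivations from the definitions and never
# call the functions they validate.

# Exhaustive pair enumeration for the time-dependent concordance.
naive_ctd <- function(cif_eval, times, events) {
  n <- length(times)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      fi <- cif_eval[i, i]
      fj <- cif_eval[i, j]
      if (fi > fj) num <- num + 1
      if (fi == fj) num <- num + 0.5
    }
  }
  num / den
}

# Exhaustive pair enumeration for the ranking loss.
naive_ranking <- function(y, bins, events, sigma) {
  Fm <- t(apply(y[, -ncol(y), drop = FALSE], 1, cumsum))
  terms <- c()
  n <- nrow(y)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (events[i] == 1 && bins[i] <= ncol(Fm) && bins[i] < bins[j]) {
      terms <- c(terms, exp(-(Fm[i, bins[i]] - Fm[j, bins[i]]) / sigma))
    }
  }
  if (length(terms) == 0) 0 else mean(terms)
}

# Term-by-term likelihood evaluation.
naive_likelihood <- function(y, bins, events) {
  nc <- ncol(y)
  v <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    Fi <- cumsum(y[i, seq_len(nc - 1)])
    p <- if (events[i] == 1) {
      y[i, min(bins[i], nc)]
    } else if (bins[i] >= nc) y[i, nc] else 1 - Fi[bins[i]]
    v[i] <- -log(max(p, 1e-12))
  }
  mean(v)
}

# A small random probability matrix over (5 bins + beyond).
random_y <- function(n, seed = 1) {
  set.seed(seed)
  y <- matrix(rexp(n * 6), n, 6)
  y / rowSums(y)
}

# Random survival-like data.
random_outcomes <- function(n, censor_frac = 0.3, seed = 1) {
  set.seed(seed)
  list(times = round(runif(n, 10, 900), 1),
       events = rbinom(n, 1, 1 - censor_frac))
}

# Tiny volume stack for preprocessing tests.
toy_stack <- function(shape = c(16, 16, 16), seed = 1) {
  generate_volume(0.05, shape = shape, seed = seed)
}

expect_close <- function(x, y, tol = 1e-8) expect_equal(x, y, tolerance = tol)
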