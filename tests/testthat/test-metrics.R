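# Evaluation statistics against brute-force oracles, hand computations and
# the survival package as an independent reference implementation.

test_that("concordance matches exhaustive pair enumeration and its extremes", {
  # perfect ordering: predicted incidence reverses observed times
  set.seed(1)
  n <- 15
  tt <- sort(runif(n, 10, 500)); ev <- rep(1L, n)
  # constant-in-time risk scores that reverse the observed order:
  # M[i, j] = risk of subject j, higher for earlier deaths
  r <- rev(seq_len(n)) / (n + 1)
  M <- matrix(r, n, n, byrow = TRUE)
  expect_equal(ctd(M, tt, ev), 1)
  # identical predictions: all ties
  flat <- matrix(0.5, n, n)
  expect_equal(ctd(flat, tt, ev), 0.5)
  # random instances equal the double-loop oracle exactly
  for (s in 1:20) {
    set.seed(s)
    m <- sample(5:30, 1)
    times <- round(runif(m, 1, 100), 1)
    events <- rbinom(m, 1, 0.7)
    Fm <- t(apply(matrix(rexp(m * 6), m, 6), 1, function(r) cumsum(r / sum(r))[1:5]))
    bins <- sample(1:5, m, replace = TRUE)
    M <- cif_at_bins(Fm, bins)
    if (sum(events) == 0) next
    expect_identical(ctd(M, times, events), naive_ctd(M, times, events))
  }
  expect_error(ctd(flat, rep(1, n), rep(0L, n)), "comparable")
})

test_that("Kaplan-Meier matches closed forms, a hand example, and survfit", {
  km <- km_estimator(c(1, 2), c(1L, 1L))
  expect_equal(sf_eval(km, c(1, 2)), c(0.5, 0))
  expect_equal(sf_eval(km_estimator(c(3, 8, 9), c(0L, 0L, 0L)), c(1, 5, 100)),
               c(1, 1, 1))
  km2 <- km_estimator(c(1, 1.5, 2, 3), c(1L, 0L, 1L, 0L))
  expect_equal(sf_eval(km2, c(1, 2)), c(0.75, 0.375))
  # no censoring: S(t) is the fraction of times exceeding t
  set.seed(2)
  tt <- sample(1:50, 30, replace = TRUE)
  km3 <- km_estimator(tt, rep(1L, 30))
  for (q in c(5, 17.5, 42)) expect_equal(sf_eval(km3, q), mean(tt > q))
  # independent reference: survival::survfit
  set.seed(3)
  tt2 <- round(rexp(40, 0.1), 1); ev2 <- rbinom(40, 1, 0.6)
  sf <- survival::survfit(survival::Surv(tt2, ev2) ~ 1)
  km4 <- km_estimator(tt2, ev2)
  expect_equal(sf_eval(km4, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("Brier score matches its closed forms and a hand-weighted example", {
  set.seed(4)
  n <- 20
  tt <- runif(n, 1, 10); ev <- rep(1L, n)
  gkm <- km_estimator(tt, 1L - ev)  # no censoring: G == 1
  for (t0 in c(2, 5, 8)) {
    oracle <- as.numeric(tt > t0)  # S_hat(t0) = 1 iff still alive
    expect_equal(brier_score(oracle, tt, ev, t0, gkm), 0)
    expect_equal(brier_score(rep(0.5, n), tt, ev, t0, gkm), 0.25)
  }
  # 5-subject censored instance, every term written out by hand
  t5 <- c(2, 4, 5, 7, 9); e5 <- c(1L, 0L, 1L, 0L, 1L)
  s5 <- c(0.9, 0.6, 0.4, 0.8, 0.7)  # predicted S(6) per subject
  G <- km_estimator(t5, 1L - e5)
  t0 <- 6
  hand <- mean(c(
    s5[1]^2 / sf_eval(G, 2, left = TRUE),  # event before 6
    0,                                     # censored at 4 (< 6): weight 0
    s5[3]^2 / sf_eval(G, 5, left = TRUE),  # event before 6
    (1 - s5[4])^2 / sf_eval(G, 6),         # alive past 6
    (1 - s5[5])^2 / sf_eval(G, 6)))        # alive past 6
  expect_equal(brier_score(s5, t5, e5, t0, G), hand, tolerance = 1e-12)
})

test_that("integrated Brier score is the normalized trapezoid and refines correctly", {
  tt <- c(1, 2, 3, 4)
  expect_equal(integrated_brier(rep(0.1, 4), tt), 0.1)
  expect_equal(integrated_brier(c(0, 0.2 / 3, 0.4 / 3, 0.2), tt), 0.1)
  # piecewise-linear integrand: fine-grid refinement gives the same integral
  set.seed(5)
  bs <- runif(6)
  times <- sort(runif(6, 1, 20))
  fine <- sort(unique(c(times, seq(times[1], times[6], length.out = 20001))))
  ref <- integrated_brier(approx(times, bs, xout = fine)$y, fine)
  expect_equal(integrated_brier(bs, times), ref, tolerance = 1e-9)
  expect_error(integrated_brier(c(1, 1), c(2, 2)), "degenerate")
})

test_that("log-rank agrees with a hand tabulation, symmetry, and survdiff", {
  # identical outcome vectors in both groups: no signal
  tt <- c(1, 3, 5, 1, 3, 5); ev <- c(1L, 1L, 0L, 1L, 1L, 0L)
  g <- c(0, 0, 0, 1, 1, 1)
  lr <- logrank_test(g, tt, ev)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  # hand-worked 6-subject example
  t6 <- c(1, 2, 3, 4, 5, 6); e6 <- c(1L, 1L, 1L, 0L, 1L, 1L)
  g6 <- c(0, 1, 0, 1, 0, 1)
  # event t=1: n1=3 (g0), n=6, d=1, O1=1, E1=1/2, V=(3/6)(3/6)(5/5)=1/4
  # event t=2: n1=2, n=5, d=1, O1=0, E1=2/5, V=(2/5)(3/5)(4/4)=6/25
  # event t=3: n1=2, n=4, d=1, O1=1, E1=1/2, V=1/4
  # event t=5: n1=1, n=2, d=1, O1=1, E1=1/2, V=1/4
  # event t=6: n1=0, n=1, d=1, O1=0, E1=0,  V=0
  oe <- (1 - 1 / 2) + (0 - 2 / 5) + (1 - 1 / 2) + (1 - 1 / 2) + 0
  vv <- 1 / 4 + 6 / 25 + 1 / 4 + 1 / 4
  lr6 <- logrank_test(g6, t6, e6)
  expect_equal(lr6$chi2, oe^2 / vv, tolerance = 1e-12)
  # independent reference on random censored data
  set.seed(6)
  tt2 <- round(rexp(60, 0.2), 2); ev2 <- rbinom(60, 1, 0.7)
  g2 <- rbinom(60, 1, 0.5)
  ref <- survival::survdiff(survival::Surv(tt2, ev2) ~ g2)
  expect_equal(logrank_test(g2, tt2, ev2)$chi2, ref$chisq, tolerance = 1e-9)
})

test_that("Cox fit maximizes the partial likelihood and matches coxph", {
  # 4-subject instance: dense grid-search oracle
  X4 <- matrix(c(1, 0, 1, 0), 4, 1)
  t4 <- c(1, 2, 3, 4); e4 <- rep(1L, 4)
  pl <- function(b) {
    lp <- X4[, 1] * b
    sum(vapply(1:4, function(i) lp[i] - log(sum(exp(lp[i:4]))), 0))
  }
  grid_b <- seq(-5, 5, by = 1e-4)
  b_star <- grid_b[which.max(vapply(grid_b, pl, 0))]
  fit <- fit_cox(X4, t4, e4)
  expect_lt(abs(fit$coef - b_star), 1e-3)
  # duplicating every subject leaves the maximizer unchanged
  fit2 <- fit_cox(rbind(X4, X4), rep(t4, 2), rep(e4, 2))
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-6)
  # reference implementation, censored + tied data
  set.seed(7)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tt <- ceiling(rexp(n, exp(0.8 * X[, 1] - 0.5 * X[, 2])) * 20)
  cc <- ceiling(runif(n, 1, quantile(tt, 0.9)))
  ev <- as.integer(tt <= cc); tobs <- pmin(tt, cc)
  fit3 <- fit_cox(X, tobs, ev)
  ref <- survival::coxph(survival::Surv(tobs, ev) ~ X, ties = "breslow")
  expect_equal(unname(fit3$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit3$var))), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_error(fit_cox(cbind(rep(1, 10)), 1:10, rep(1L, 10)), "constant")
})

test_that("Schoenfeld residuals sum to zero and the test tracks cox.zph", {
  set.seed(8)
  n <- 200
  a <- rnorm(n); b <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(0.6 * a - 0.4 * b))
  cc <- runif(n, 0, quantile(tt, 0.9))
  ev <- as.integer(tt <= cc); tobs <- pmin(tt, cc)
  fit <- fit_cox(cbind(a = a, b = b), tobs, ev)
  sr <- gliosurv:::schoenfeld_residuals(fit)
  expect_lt(max(abs(colSums(sr$resid))), 1e-6)
  z <- schoenfeld_ph_test(fit)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(tobs, ev) ~ a + b, ties = "breslow"),
    transform = "km")
  expect_equal(unname(z$chi2), unname(ref$table[1:2, "chisq"]), tolerance = 0.02)
  expect_equal(unname(z$p), unname(ref$table[1:2, "p"]), tolerance = 0.02)
  expect_error(schoenfeld_ph_test(fit_cox(cbind(a = a[1:5]), tobs[1:5],
                                          c(1L, 1L, 0L, 0L, 0L))),
               "3 events")
})

test_that("dichotomization follows the predicted-median rule", {
  horizon <- 24
  always_up <- rep(1, horizon)
  drop6 <- c(rep(0.9, 5), rep(0.4, horizon - 5))
  drop12 <- c(seq(1, 0.51, length.out = 11), rep(0.49, horizon - 11))
  m <- rbind(always_up, drop6, drop12)
  g <- dichotomize(m, threshold_months = 12)
  expect_equal(as.character(g), c("favorable", "unfavorable", "unfavorable"))
})
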