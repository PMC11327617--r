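# From-scratch survival evaluation statistics. Conventions used throughout:
# deaths precede censorings at tied times in all risk-set bookkeeping, and
# risk sets are {i : time_i >= t}.

#' Evaluate per-subject CIFs at every subject's bin
#'
#' Builds the square matrix `M[i, j] = F_j(bin_i)` needed by [ctd()].
#'
#' @param cif_matrix subjects x bins matrix of cumulative incidence values.
#' @param bins integer bin per subject.
#' @return n x n matrix.
#' @export
cif_at_bins <- function(cif_matrix, bins) {
  stopifnot(nrow(cif_matrix) == length(bins), all(bins >= 1L),
            all(bins <= ncol(cif_matrix)))
  t(cif_matrix[, bins, drop = FALSE])
}

#' Time-dependent concordance index
#'
#' Antolini-style extension of Harrell's C: over comparable pairs (i, j)
#' with `time_i < time_j` and `event_i = 1`, the pair is concordant when the
#' predicted cumulative incidence at subject i's own bin is higher for i than
#' for j (`M[i, i] > M[i, j]`); exact ties count 1/2.
#'
#' @param cif_eval n x n matrix with `M[i, j] = F_j(bin_i)`, see
#'   [cif_at_bins()].
#' @param times,events observed outcomes.
#' @return concordant pair fraction in `[0, 1]`.
#' @export
ctd <- function(cif_eval, times, events) {
  n <- length(times)
  stopifnot(nrow(cif_eval) == n, ncol(cif_eval) == n, length(events) == n)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1L) next
    comp <- which(times > times[i])
    if (length(comp) == 0L) next
    di <- cif_eval[i, i] - cif_eval[i, comp]
    num <- num + sum(di > 0) + 0.5 * sum(di == 0)
    den <- den + length(comp)
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times,events observed outcomes (`event = 1` death, `0` censored).
#' @return a `step_function` with `jump_times` (distinct event times) and
#'   `values` (survival after each jump); evaluate with [sf_eval()].
#' @export
km_estimator <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  et <- sort(unique(times[events == 1L]))
  surv <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    n_at <- sum(times >= et[k])
    d <- sum(times == et[k] & events == 1L)
    s <- s * (1 - d / n_at)
    surv[k] <- s
  }
  structure(list(jump_times = et, values = surv), class = "step_function")
}

#' Evaluate a right-continuous step function
#'
#' @param sf a `step_function` (initial value 1 before the first jump).
#' @param t evaluation time(s).
#' @param left evaluate the left limit `S(t-)` instead of `S(t)`.
#' @return numeric value(s).
#' @export
sf_eval <- function(sf, t, left = FALSE) {
  idx <- findInterval(t, sf$jump_times, left.open = left)
  ifelse(idx == 0L, 1, sf$values[pmax(idx, 1L)])
}

#' Censoring-weighted Brier score at a time point
#'
#' Graf-style inverse-probability-of-censoring weighting: subjects with an
#' event at or before `t` contribute `S_hat(t)^2 / G(time-)`, subjects still
#' under observation past `t` contribute `(1 - S_hat(t))^2 / G(t)`, and
#' subjects censored before `t` contribute 0.
#'
#' @param surv_at_t predicted `S(t)` per subject.
#' @param times,events observed outcomes.
#' @param t evaluation time.
#' @param censor_km `step_function` for the censoring distribution `G`
#'   (Kaplan-Meier with the event indicator flipped); fitted by the caller,
#'   typically on the same split.
#' @return Brier score in `[0, 1]` (up to weighting).
#' @export
brier_score <- function(surv_at_t, times, events, t, censor_km) {
  n <- length(times)
  stopifnot(length(surv_at_t) == n, length(events) == n)
  contrib <- numeric(n)
  gt <- sf_eval(censor_km, t)
  for (i in seq_len(n)) {
    if (times[i] <= t && events[i] == 1L) {
      gi <- sf_eval(censor_km, times[i], left = TRUE)
      if (gi <= 0) stop("censoring survival G is zero at a needed time")
      contrib[i] <- surv_at_t[i]^2 / gi
    } else if (times[i] > t) {
      if (gt <= 0) stop("censoring survival G is zero at a needed time")
      contrib[i] <- (1 - surv_at_t[i])^2 / gt
    }  # censored at or before t: weight 0
  }
  mean(contrib)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of `BS(t)` over the evaluation times, divided by the
#' time range.
#'
#' @param brier Brier scores at the evaluation times.
#' @param eval_times increasing evaluation times (>= 2).
#' @return scalar IBS.
#' @export
integrated_brier <- function(brier, eval_times) {
  stopifnot(length(brier) == length(eval_times), length(eval_times) >= 2L)
  rng <- diff(range(eval_times))
  if (rng <= 0) stop("degenerate time range")
  sum(diff(eval_times) * (utils::head(brier, -1) + utils::tail(brier, -1)) / 2) / rng
}

#' Two-group log-rank test
#'
#' @param groups two-level grouping (factor, character or 0/1).
#' @param times,events observed outcomes.
#' @return list with `chi2` and `p` (chi-square, 1 df).
#' @export
logrank_test <- function(groups, times, events) {
  g <- as.integer(factor(groups))
  if (length(unique(g)) != 2L) stop("exactly two nonempty groups required")
  et <- sort(unique(times[events == 1L]))
  oe <- v <- 0
  for (tk in et) {
    at <- times >= tk
    n1 <- sum(at & g == 1L); n2 <- sum(at & g == 2L)
    nn <- n1 + n2
    d <- sum(times == tk & events == 1L)
    d1 <- sum(times == tk & events == 1L & g == 1L)
    oe <- oe + d1 - d * n1 / nn
    if (nn > 1L) v <- v + d * (n1 / nn) * (n2 / nn) * (nn - d) / (nn - 1L)
  }
  chi2 <- if (v > 0) oe^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

# Risk-set sums S0 = sum w, S1 = sum w x, S2 = sum w x x' over {time >= t}.
cox_risk_sums <- function(X, times, lp) {
  ord <- order(times, decreasing = TRUE)
  w <- exp(lp)
  p <- ncol(X)
  n <- nrow(X)
  S0 <- numeric(n); S1 <- matrix(0, n, p); S2 <- array(0, c(n, p, p))
  s0 <- 0; s1 <- numeric(p); s2 <- matrix(0, p, p)
  for (k in seq_len(n)) {
    i <- ord[k]
    s0 <- s0 + w[i]
    s1 <- s1 + w[i] * X[i, ]
    s2 <- s2 + w[i] * tcrossprod(X[i, ])
    S0[i] <- s0; S1[i, ] <- s1; S2[i, , ] <- s2
  }
  # ties: all subjects sharing a time must see the full risk set sum
  for (tt in unique(times[duplicated(times)])) {
    idx <- which(times == tt)
    j <- idx[which.max(S0[idx])]
    for (i in idx) { S0[i] <- S0[j]; S1[i, ] <- S1[j, ]; S2[i, , ] <- S2[j, , ] }
  }
  list(S0 = S0, S1 = S1, S2 = S2)
}

#' Cox proportional-hazards fit (Breslow partial likelihood)
#'
#' Newton-Raphson maximization of the Breslow-tie partial likelihood;
#' convergence when the largest score component falls below 1e-8.
#'
#' @param X covariate matrix (no constant columns).
#' @param times,events observed outcomes (at least one event).
#' @return a `cox_fit`: `coef`, `var` (inverse information), `info`,
#'   `loglik`, `iter`, plus the data for residual diagnostics.
#' @export
fit_cox <- function(X, times, events) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(times) == n, length(events) == n)
  if (sum(events) < 1L) stop("no events")
  if (any(apply(X, 2L, stats::sd) < 1e-12)) stop("constant covariate column")
  beta <- numeric(p)
  ev <- which(events == 1L)
  for (iter in seq_len(100L)) {
    lp <- drop(X %*% beta)
    rs <- cox_risk_sums(X, times, lp)
    xbar <- rs$S1[ev, , drop = FALSE] / rs$S0[ev]
    score <- colSums(X[ev, , drop = FALSE] - xbar)
    info <- matrix(0, p, p)
    for (i in ev) {
      info <- info + rs$S2[i, , ] / rs$S0[i] - tcrossprod(rs$S1[i, ] / rs$S0[i])
    }
    if (max(abs(score)) < 1e-8) {
      loglik <- sum(lp[ev]) - sum(log(rs$S0[ev]))
      return(structure(list(coef = beta, var = solve(info), info = info,
                            loglik = loglik, iter = iter, X = X,
                            times = times, events = events),
                       class = "cox_fit"))
    }
    step <- solve(info, score)
    beta <- beta + step
    if (any(abs(beta) > 30)) stop("Cox fit diverged (possible separation)")
  }
  stop("Cox fit did not converge in 100 iterations")
}

# Schoenfeld residuals (one row per event, ordered by event time) and the
# per-event risk-set covariance matrices V(t_k).
schoenfeld_residuals <- function(fit) {
  lp <- drop(fit$X %*% fit$coef)
  rs <- cox_risk_sums(fit$X, fit$times, lp)
  ev <- which(fit$events == 1L)
  ev <- ev[order(fit$times[ev])]
  p <- ncol(fit$X)
  r <- matrix(0, length(ev), p)
  V <- array(0, c(length(ev), p, p))
  for (k in seq_along(ev)) {
    i <- ev[k]
    xb <- rs$S1[i, ] / rs$S0[i]
    r[k, ] <- fit$X[i, ] - xb
    V[k, , ] <- rs$S2[i, , ] / rs$S0[i] - tcrossprod(xb)
  }
  list(resid = r, V = V, times = fit$times[ev])
}

#' Schoenfeld proportional-hazards test
#'
#' Grambsch-Therneau score test for a time-varying coefficient
#' `beta(t) = beta + theta * g(t)` with the Kaplan-Meier transform
#' `g(t) = 1 - KM(t-)`; one chi-square (1 df) statistic per covariate.
#'
#' @param fit a converged `cox_fit`.
#' @return list with `chi2` and `p` per covariate, and the transformed times.
#' @export
schoenfeld_ph_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  sr <- schoenfeld_residuals(fit)
  d <- nrow(sr$resid)
  if (d < 3L) stop("need at least 3 events for the proportionality test")
  km <- km_estimator(fit$times, fit$events)
  g <- 1 - sf_eval(km, sr$times, left = TRUE)
  gc <- g - mean(g)
  p <- ncol(sr$resid)
  u <- drop(t(gc) %*% sr$resid)
  chi2 <- pv <- numeric(p)
  for (j in seq_len(p)) {
    denom <- sum(gc^2 * sr$V[, j, j])  # exact per-event risk-set variances
    chi2[j] <- u[j]^2 / denom
    pv[j] <- stats::pchisq(chi2[j], 1L, lower.tail = FALSE)
  }
  names(chi2) <- names(pv) <- colnames(fit$X)
  list(chi2 = chi2, p = pv, transform = g)
}

#' Dichotomize subjects by predicted median survival
#'
#' Predicted median = first month at which the monthly survival curve drops
#' below 0.5 (infinite if it never does); a subject is "favorable" iff the
#' predicted median strictly exceeds the threshold.
#'
#' @param monthly matrix (subjects x months) of monthly survival values.
#' @param threshold_months dichotomization threshold (training-median
#'   survival; 12 months by default).
#' @return factor with levels `unfavorable`, `favorable`.
#' @export
dichotomize <- function(monthly, threshold_months = 12) {
  if (!is.matrix(monthly)) monthly <- matrix(monthly, nrow = 1L)
  med <- apply(monthly, 1L, function(s) {
    k <- which(s < 0.5)
    if (length(k) == 0L) Inf else k[1L]
  })
  factor(ifelse(med > threshold_months, "favorable", "unfavorable"),
         levels = c("unfavorable", "favorable"))
}
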