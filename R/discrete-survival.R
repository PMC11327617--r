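# Discrete-time survival head: percentile time grid, softmax cell
# probabilities over (event, time-bin) cells plus a beyond-horizon cell,
# cumulative incidence, survival curves with monthly interpolation, and the
# two-part (likelihood + ranking) training loss.

DAYS_PER_MONTH <- 30.44

#' Build the discrete time grid from training survival times
#'
#' Cut points are the 10th/30th/50th/70th/90th percentiles (linear
#' interpolation quantiles) of the observed times, events and censored
#' pooled. A sixth beyond-horizon cell represents survival past the last
#' cut point.
#'
#' @param training_times observed times (days) of the training split
#'   (>= 10 subjects).
#' @param probs quantile levels defining the cut points.
#' @return a `time_grid`: `cut_points`, `t_max`, `month_days`.
#' @export
build_time_grid <- function(training_times, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(training_times) < 10L) stop("need at least 10 training subjects")
  cuts <- unname(stats::quantile(training_times, probs, type = 7))
  cuts <- unique(cuts)
  if (length(cuts) < 3L) stop("degenerate training times: fewer than 3 distinct cut points")
  if (any(cuts <= 0)) stop("cut points must be positive")
  structure(list(cut_points = cuts, t_max = cuts[length(cuts)],
                 month_days = DAYS_PER_MONTH),
            class = "time_grid")
}

#' Map a continuous time to its discrete bin
#'
#' Bins are right-closed: bin m covers `(cut_{m-1}, cut_m]` with `cut_0 = 0`;
#' times past the last cut point map to the beyond-horizon bin
#' (`length(cut_points) + 1`).
#'
#' @param t nonnegative time in days.
#' @param grid a `time_grid` (or list with `cut_points`).
#' @return integer bin index.
#' @export
discretize_time <- function(t, grid) {
  if (t < 0) stop("negative time")
  cuts <- grid$cut_points
  b <- findInterval(t, cuts, left.open = TRUE) + 1L
  # findInterval with left.open counts cuts < t strictly, so t == cut_m
  # lands in bin m (right-closed convention); t = 0 lands in bin 1.
  as.integer(b)
}

#' Softmax over the output cells
#'
#' Max-subtracted softmax; rows of a matrix are treated as independent
#' subjects.
#'
#' @param logits numeric vector or matrix (subjects x cells).
#' @return probabilities of the same shape, each subject summing to 1.
#' @export
softmax_probabilities <- function(logits) {
  if (!is.matrix(logits)) {
    e <- exp(logits - max(logits))
    return(e / sum(e))
  }
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' Cumulative incidence from cell probabilities
#'
#' `F(bin) = sum_{m <= bin} y_m` over the in-horizon cells; the beyond cell
#' is the survival mass at the horizon (`F(last) = 1 - y_beyond`).
#'
#' @param y probability vector (length bins + 1) or matrix.
#' @param bin bin index in `1..bins`; if missing, the full CIF over all
#'   in-horizon bins is returned.
#' @return CIF value(s) in `[0, 1]`.
#' @export
cif <- function(y, bin = NULL) {
  if (is.matrix(y)) {
    Fm <- t(apply(y[, -ncol(y), drop = FALSE], 1L, cumsum))
    return(if (is.null(bin)) Fm else Fm[, bin])
  }
  Fm <- cumsum(y[-length(y)])
  if (is.null(bin)) Fm else Fm[bin]
}

#' Survival function on the grid
#'
#' `S(cut_m) = 1 - F(m)`; the value at the horizon equals the beyond-horizon
#' cell probability.
#'
#' @param y probability vector or matrix (subjects x cells).
#' @return survival value(s) per cut point (vector or matrix).
#' @export
survival_function <- function(y) {
  Fm <- cif(y)
  1 - Fm
}

#' Interpolate a grid survival curve to monthly resolution
#'
#' An anchor `(0, 1)` is prepended and the curve is piecewise-linear in days;
#' it is sampled at integer months (1 month = 30.44 days) up to the horizon.
#'
#' @param grid_survival survival values at the cut points (vector, or matrix
#'   subjects x cut points).
#' @param grid a `time_grid`.
#' @return vector (or matrix) of monthly survival probabilities; column
#'   names give the month index.
#' @export
interpolate_monthly <- function(grid_survival, grid) {
  cuts <- grid$cut_points
  months <- seq_len(floor(grid$t_max / grid$month_days))
  qd <- months * grid$month_days
  interp1 <- function(sv) {
    stats::approx(c(0, cuts), c(1, sv), xout = qd, method = "linear")$y
  }
  if (is.matrix(grid_survival)) {
    out <- t(apply(grid_survival, 1L, interp1))
    colnames(out) <- paste0("m", months)
    return(out)
  }
  stats::setNames(interp1(grid_survival), paste0("m", months))
}

#' Discrete-time likelihood loss
#'
#' Mean negative log-likelihood: an event in bin b contributes
#' `-log y_b`; a subject censored in bin b contributes `-log(1 - F(b))`
#' (censored beyond the horizon: `-log y_beyond`, consistent with
#' `S(t_max) = y_beyond`). Probabilities are floored at 1e-12 inside logs.
#'
#' @param y_batch matrix (subjects x cells) of cell probabilities.
#' @param bins integer bin per subject (from [discretize_time()]).
#' @param events 0/1 event indicator.
#' @return nonnegative scalar.
#' @export
likelihood_loss <- function(y_batch, bins, events) {
  n <- nrow(y_batch)
  ncell <- ncol(y_batch)
  stopifnot(length(bins) == n, length(events) == n, all(events %in% 0:1))
  Fm <- cif(y_batch)
  ll <- numeric(n)
  for (i in seq_len(n)) {
    b <- bins[i]
    p <- if (events[i] == 1L) {
      y_batch[i, b]
    } else if (b >= ncell) {
      y_batch[i, ncell]
    } else {
      1 - Fm[i, b]
    }
    ll[i] <- -log(max(p, 1e-12))
  }
  mean(ll)
}

#' Pairwise ranking loss on the cumulative incidence
#'
#' Over acceptable pairs (i, j) with `event_i = 1` and `bin_i < bin_j`, the
#' mean of `exp(-(F_i(bin_i) - F_j(bin_i)) / sigma)`: a correctly ordered
#' pair (higher predicted incidence for the subject who died first) is
#' rewarded exponentially. Zero when no acceptable pair exists.
#'
#' @inheritParams likelihood_loss
#' @param sigma positive scale of the exponential penalty.
#' @return nonnegative scalar.
#' @export
ranking_loss <- function(y_batch, bins, events, sigma = 0.1) {
  stopifnot(sigma > 0)
  n <- nrow(y_batch)
  Fm <- cif(y_batch)
  nb <- ncol(Fm)
  terms <- c()
  for (i in seq_len(n)) {
    if (events[i] != 1L || bins[i] > nb) next
    for (j in seq_len(n)) {
      if (bins[j] > bins[i]) {
        terms <- c(terms, exp(-(Fm[i, bins[i]] - Fm[j, bins[i]]) / sigma))
      }
    }
  }
  if (length(terms) == 0L) 0 else mean(terms)
}

#' Combined survival training loss
#'
#' @param L1 likelihood loss, [likelihood_loss()].
#' @param L2 ranking loss, [ranking_loss()].
#' @param lambda_rank nonnegative weight of the ranking term.
#' @return `L1 + lambda_rank * L2`.
#' @export
total_loss <- function(L1, L2, lambda_rank = 0.5) {
  stopifnot(lambda_rank >= 0)
  L1 + lambda_rank * L2
}
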