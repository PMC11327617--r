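# Imaging and covariate preprocessing. Every fitted statistic (intensity
# landmarks, continuous ranges, category maps) derives from the training
# split only; the fitted objects are frozen and applying them never re-fits.

#' Stack the four MR contrasts into one channel-first volume
#'
#' Channel order is fixed by convention as (T1, T1c, T2, FLAIR).
#'
#' @param t1,t1c,t2,flair single-channel volumes: 3D arrays or lists with
#'   `data` (3D array) and `spacing` (mm triple).
#' @param brain_mask optional logical 3D array; defaults to voxels that are
#'   nonzero in any channel.
#' @return a `volume_stack`.
#' @export
stack_modalities <- function(t1, t1c, t2, flair, brain_mask = NULL) {
  grab <- function(v) {
    if (is.list(v)) list(data = v$data, spacing = v$spacing)
    else list(data = v, spacing = attr(v, "spacing") %||% c(1, 1, 1))
  }
  vols <- lapply(list(t1, t1c, t2, flair), grab)
  shp <- dim(vols[[1L]]$data)
  spc <- vols[[1L]]$spacing
  for (v in vols[-1L]) {
    if (!identical(dim(v$data), shp)) stop("modality volumes differ in shape")
    if (max(abs(v$spacing - spc)) > 1e-9) stop("modality volumes differ in voxel spacing")
  }
  data <- array(0, dim = c(4L, shp))
  for (ch in 1:4) data[ch, , , ] <- vols[[ch]]$data
  if (is.null(brain_mask)) {
    brain_mask <- apply(abs(data) > 0, c(2L, 3L, 4L), any)
  }
  if (!any(brain_mask)) stop("empty brain mask")
  structure(list(data = data, spacing = spc, brain_mask = brain_mask),
            class = "volume_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-normalize each channel within the brain mask
#'
#' Per channel, within-mask intensities get mean 0 and (population) sd 1;
#' voxels outside the mask are set to 0.
#'
#' @param stack a `volume_stack`.
#' @return the normalized `volume_stack`.
#' @export
znorm_volume <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  mask <- stack$brain_mask
  if (sum(mask) < 2L) stop("brain mask needs at least 2 voxels")
  shp <- dim(stack$data)[-1L]
  for (ch in seq_len(dim(stack$data)[1L])) {
    vals <- array(stack$data[ch, , , ], dim = shp)
    v <- vals[mask]
    sdv <- sqrt(mean((v - mean(v))^2))
    if (sdv < 1e-12) stop("zero within-mask variance in channel ", ch)
    out <- array(0, dim = shp)
    out[mask] <- (v - mean(v)) / sdv
    stack$data[ch, , , ] <- out
  }
  stack
}

#' Fit per-channel decile landmarks for histogram standardization
#'
#' Landmarks are the mean of the subjects' within-mask deciles per channel,
#' computed on the training split only (Nyul-style).
#'
#' @param stacks list of training `volume_stack`s.
#' @param probs landmark quantile levels.
#' @return a `hist_landmarks` object.
#' @export
fit_histogram_landmarks <- function(stacks, probs = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(stacks) >= 1L)
  nchan <- dim(stacks[[1L]]$data)[1L]
  lm <- matrix(0, nchan, length(probs))
  for (st in stacks) {
    for (ch in seq_len(nchan)) {
      lm[ch, ] <- lm[ch, ] +
        stats::quantile(st$data[ch, , , ][st$brain_mask], probs, type = 7)
    }
  }
  structure(list(landmarks = lm / length(stacks), probs = probs,
                 fitted = TRUE), class = "hist_landmarks")
}

#' Histogram standardization against training landmarks
#'
#' Piecewise-linear intensity mapping aligning the subject's within-mask
#' deciles to the training-average deciles, per channel; the end segments
#' extrapolate linearly. The map is monotone, so intensity ordering is
#' preserved.
#'
#' @param stack a `volume_stack`.
#' @param landmarks a fitted `hist_landmarks`.
#' @return the standardized `volume_stack`.
#' @export
histogram_standardize <- function(stack, landmarks) {
  if (!inherits(landmarks, "hist_landmarks") || !isTRUE(landmarks$fitted)) {
    stop("landmarks have not been fitted")
  }
  mask <- stack$brain_mask
  shp <- dim(stack$data)[-1L]
  for (ch in seq_len(dim(stack$data)[1L])) {
    vals <- array(stack$data[ch, , , ], dim = shp)
    v <- vals[mask]
    own <- stats::quantile(v, landmarks$probs, type = 7)
    tgt <- landmarks$landmarks[ch, ]
    keep <- !duplicated(own)
    own <- own[keep]; tgt <- tgt[keep]
    if (length(own) < 2L) stop("degenerate intensity distribution in channel ", ch)
    # linear extrapolation beyond the outer landmarks using the end slopes
    slope_lo <- (tgt[2L] - tgt[1L]) / (own[2L] - own[1L])
    k <- length(own)
    slope_hi <- (tgt[k] - tgt[k - 1L]) / (own[k] - own[k - 1L])
    mapped <- stats::approx(own, tgt, xout = v, rule = 2)$y
    lo <- v < own[1L]; hi <- v > own[k]
    mapped[lo] <- tgt[1L] + slope_lo * (v[lo] - own[1L])
    mapped[hi] <- tgt[k] + slope_hi * (v[hi] - own[k])
    out <- vals
    out[mask] <- mapped
    stack$data[ch, , , ] <- out
  }
  stack
}

#' Scale a continuous covariate to [-1, 1]
#'
#' `x -> 2 (x - min) / (max - min) - 1`, with the range fitted on the
#' training split; out-of-range values are clipped.
#'
#' @param values numeric vector.
#' @param range length-2 `(min, max)` with `max > min`.
#' @return values in `[-1, 1]`.
#' @export
scale_continuous <- function(values, range) {
  if (range[2L] <= range[1L]) stop("degenerate range: max must exceed min")
  out <- 2 * (values - range[1L]) / (range[2L] - range[1L]) - 1
  pmin(pmax(out, -1), 1)
}

#' One-hot encode a categorical value
#'
#' The category map must carry an explicit `"missing"` level; `NA` maps to
#' it, and a category unseen at fit time maps to it with a warning.
#'
#' @param value character value (or `NA`).
#' @param category_map ordered character vector of levels incl. `"missing"`.
#' @return 0/1 indicator vector summing to 1.
#' @export
one_hot <- function(value, category_map) {
  if (!"missing" %in% category_map) stop("category_map must include a 'missing' level")
  out <- stats::setNames(numeric(length(category_map)), category_map)
  if (is.na(value)) {
    out["missing"] <- 1
  } else if (value %in% category_map) {
    out[value] <- 1
  } else {
    warning("unseen category '", value, "' mapped to 'missing'")
    out["missing"] <- 1
  }
  out
}

#' Fit the covariate encoding on the training split
#'
#' Continuous variables get a `(min, max)` range for [-1, 1] scaling;
#' categorical variables get an ordered category list with an explicit
#' `"missing"` level.
#'
#' @param df training data frame.
#' @param continuous names of continuous columns.
#' @param categorical names of categorical columns.
#' @return a frozen `covariate_encoding`.
#' @export
fit_covariate_encoding <- function(df, continuous = "age",
                                   categorical = c("sex", "gtr", "mgmt", "idh", "kps")) {
  ranges <- lapply(continuous, function(v) range(df[[v]], na.rm = TRUE))
  names(ranges) <- continuous
  for (v in continuous) {
    if (ranges[[v]][2L] <= ranges[[v]][1L]) stop("degenerate range for ", v)
  }
  maps <- lapply(categorical, function(v) {
    c(sort(unique(stats::na.omit(df[[v]]))), "missing")
  })
  names(maps) <- categorical
  structure(list(continuous_ranges = ranges, category_maps = maps,
                 fitted = TRUE), class = "covariate_encoding")
}

#' Apply a fitted covariate encoding
#'
#' @param df data frame with the encoded columns.
#' @param enc a fitted `covariate_encoding` (never re-fit here).
#' @return numeric design matrix (scaled continuous + one-hot blocks).
#' @export
encode_covariates <- function(df, enc) {
  if (!inherits(enc, "covariate_encoding") || !isTRUE(enc$fitted)) {
    stop("covariate encoding has not been fitted")
  }
  blocks <- list()
  for (v in names(enc$continuous_ranges)) {
    blocks[[v]] <- matrix(scale_continuous(df[[v]], enc$continuous_ranges[[v]]),
                          ncol = 1L, dimnames = list(NULL, v))
  }
  for (v in names(enc$category_maps)) {
    map <- enc$category_maps[[v]]
    m <- t(vapply(df[[v]], one_hot, numeric(length(map)), category_map = map))
    colnames(m) <- paste0(v, ".", map)
    blocks[[v]] <- m
  }
  do.call(cbind, blocks)
}
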