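# Synthetic multimodal glioblastoma cohorts with known ground truth.
#
# The generator emulates the statistical structure the survival model
# assumes: tabular covariates with stated log-hazard-ratio effects, an
# imaging channel whose lesion volume fraction enters the hazard linearly,
# discrete-time hazards on a fixed day grid, and independent uniform right
# censoring calibrated to a target censored fraction.

# Default generation grid (days) and per-bin baseline hazards: chosen to give
# a median overall survival near 12 months with realistic spread.
default_cut_points <- function() c(120, 240, 365, 540, 730)
default_baseline_logit_hazard <- function() stats::qlogis(c(0.15, 0.25, 0.30, 0.35, 0.40))

#' Synthetic cohort configuration
#'
#' @param n_subjects cohort size (>= 2).
#' @param volume_shape integer triple; each axis must be divisible by the
#'   encoder patch size in downstream use. `NULL` for tabular-only cohorts.
#' @param n_channels number of MR contrasts per subject.
#' @param beta_clinical log-hazard ratio per encoded clinical covariate
#'   (age_z, male, gtr, mgmt_methylated, idh_wildtype, kps_high).
#' @param beta_imaging log-hazard ratio per standard deviation of lesion
#'   volume fraction.
#' @param baseline_logit_hazard per-bin baseline hazard on the logit scale.
#' @param cut_points increasing day grid bounding the discrete bins.
#' @param censoring_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects,
                         volume_shape = c(32L, 32L, 32L),
                         n_channels = 4L,
                         beta_clinical = c(0.4, 0.1, -0.5, -0.5, 0.6, -0.3),
                         beta_imaging = 0.8,
                         baseline_logit_hazard = default_baseline_logit_hazard(),
                         cut_points = default_cut_points(),
                         censoring_rate = 0.3,
                         seed = 1L) {
  stopifnot(n_subjects >= 2L, censoring_rate >= 0, censoring_rate < 1,
            length(baseline_logit_hazard) == length(cut_points),
            all(diff(cut_points) > 0), all(cut_points > 0))
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = if (is.null(volume_shape)) NULL else as.integer(volume_shape),
                 n_channels = as.integer(n_channels),
                 beta_clinical = beta_clinical, beta_imaging = beta_imaging,
                 baseline_logit_hazard = baseline_logit_hazard,
                 cut_points = cut_points,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate clinical/molecular covariates with known effects
#'
#' Emulates the covariate mix of multicenter glioblastoma cohorts: age
#' (normal, mean 63, sd 12, truncated to 18-90), sex (60% male), extent of
#' resection (57% GTR), MGMT promoter methylation (50% methylated, 20%
#' missing), IDH status (90% wild-type), KPS >= 80 (60%, 30% missing).
#' Missingness is completely at random; in the encoded design used for the
#' ground-truth linear predictor a missing value sits at the reference level.
#'
#' @param n number of subjects (>= 2).
#' @param effects numeric vector of length 6, log-hazard ratio per encoded
#'   covariate (age_z, male, gtr, mgmt_methylated, idh_wildtype, kps_high).
#' @param seed integer seed.
#' @return list with `table` (human-readable covariates), `X` (encoded
#'   numeric design), and `lp` (linear predictor `X %*% effects`).
#' @export
generate_clinical <- function(n, effects, seed = 1L) {
  stopifnot(n >= 2L)
  if (length(effects) != 6L) {
    stop("effects must have length 6 (encoded covariate dimension), got ",
         length(effects))
  }
  set.seed(seed)
  age <- stats::rnorm(n, 63, 12)
  age <- pmin(pmax(age, 18), 90)
  male <- stats::rbinom(n, 1L, 0.6)
  gtr <- stats::rbinom(n, 1L, 0.57)
  mgmt <- stats::rbinom(n, 1L, 0.5)
  mgmt[stats::runif(n) < 0.2] <- NA
  idh_wt <- stats::rbinom(n, 1L, 0.9)
  kps <- stats::rbinom(n, 1L, 0.6)
  kps[stats::runif(n) < 0.3] <- NA
  X <- cbind(age_z = (age - 63) / 12,
             male = male,
             gtr = gtr,
             mgmt_methylated = ifelse(is.na(mgmt), 0L, mgmt),
             idh_wildtype = idh_wt,
             kps_high = ifelse(is.na(kps), 0L, kps))
  tab <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = age,
    sex = ifelse(male == 1L, "male", "female"),
    gtr = ifelse(gtr == 1L, "GTR", "non-GTR"),
    mgmt = ifelse(is.na(mgmt), NA_character_,
                  ifelse(mgmt == 1L, "methylated", "unmethylated")),
    idh = ifelse(idh_wt == 1L, "wildtype", "mutant"),
    kps = ifelse(is.na(kps), NA_character_, ifelse(kps == 1L, ">=80", "<80")),
    stringsAsFactors = FALSE
  )
  list(table = tab, X = X, lp = drop(X %*% effects))
}

#' Generate a 4-channel synthetic brain volume with a lesion
#'
#' The "brain" is an ellipsoid of Gaussian-noise intensity inside a zero
#' exterior; the lesion is the ball of voxels nearest a random center whose
#' count matches `imaging_feature_target * brain voxels` (exact up to one
#' voxel of quantization). Lesion intensity is offset per channel by
#' `channel_contrasts`, mimicking the differing lesion appearance across
#' T1, T1c, T2 and FLAIR.
#'
#' @param imaging_feature_target lesion volume fraction in `[0, 0.2]`.
#' @param shape integer triple, >= 16 per axis.
#' @param channel_contrasts intensity offset of lesion voxels per channel.
#' @param seed integer seed.
#' @return a `volume_stack`: `data` (channels, X, Y, Z), `spacing`,
#'   `brain_mask`, `lesion_mask`, `lesion_fraction`.
#' @export
generate_volume <- function(imaging_feature_target, shape = c(32L, 32L, 32L),
                            channel_contrasts = c(-0.4, 0.8, 0.6, 0.7),
                            seed = 1L) {
  stopifnot(imaging_feature_target >= 0, imaging_feature_target <= 0.2,
            all(shape >= 16L))
  shape <- as.integer(shape)
  nchan <- length(channel_contrasts)
  set.seed(seed)
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  gx <- seq_len(shape[1L]); gy <- seq_len(shape[2L]); gz <- seq_len(shape[3L])
  exg <- expand.grid(x = gx, y = gy, z = gz)
  ell <- ((exg$x - ctr[1L]) / semi[1L])^2 + ((exg$y - ctr[2L]) / semi[2L])^2 +
    ((exg$z - ctr[3L]) / semi[3L])^2
  brain <- array(ell <= 1, dim = shape)
  nb <- sum(brain)
  data <- array(0, dim = c(nchan, shape))
  for (ch in seq_len(nchan)) {
    vals <- array(0, dim = shape)
    vals[brain] <- stats::rnorm(nb, mean = 1, sd = 0.1)
    data[ch, , , ] <- vals
  }
  lesion <- array(FALSE, dim = shape)
  n_lesion <- round(imaging_feature_target * nb)
  if (n_lesion > 0L) {
    lcen <- ctr + stats::runif(3L, -0.1, 0.1) * shape
    d2 <- (exg$x - lcen[1L])^2 + (exg$y - lcen[2L])^2 + (exg$z - lcen[3L])^2
    sel <- order(d2)[seq_len(n_lesion)]
    if (any(!brain[sel])) {
      stop("lesion sphere exceeds the brain ellipsoid; reduce the target fraction")
    }
    lesion[sel] <- TRUE
    for (ch in seq_len(nchan)) {
      vals <- data[ch, , , ]
      vals[lesion] <- vals[lesion] + channel_contrasts[ch]
      data[ch, , , ] <- vals
    }
  }
  structure(list(data = data, spacing = c(1, 1, 1), brain_mask = brain,
                 lesion_mask = lesion, lesion_fraction = n_lesion / nb),
            class = "volume_stack")
}

#' Sample discrete-time survival outcomes from known hazards
#'
#' Per-bin hazard is `plogis(baseline_logit_hazard[m] + lp)`; the event bin
#' is sampled sequentially, the continuous event time uniformly within the
#' bin (subjects surviving the grid get a time uniformly beyond the horizon).
#' Independent uniform censoring on `[0, c]` is calibrated by root finding so
#' the expected censored fraction matches `censoring_rate`.
#'
#' @param lp linear predictor per subject.
#' @param cut_points increasing day grid.
#' @param baseline_logit_hazard per-bin logit baseline hazard.
#' @param censoring_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `time_days`, `event` (1 death, 0 censored), `event_bin`
#'   (true bin incl. beyond-horizon), `hazard` (n x bins matrix of true
#'   hazards), `censor_horizon`.
#' @export
sample_survival <- function(lp, cut_points = default_cut_points(),
                            baseline_logit_hazard = default_baseline_logit_hazard(),
                            censoring_rate = 0.3, seed = 1L) {
  stopifnot(length(cut_points) >= 1L, censoring_rate >= 0, censoring_rate < 1,
            length(baseline_logit_hazard) == length(cut_points))
  n <- length(lp)
  m <- length(cut_points)
  set.seed(seed)
  H <- stats::plogis(outer(lp, baseline_logit_hazard, "+"))
  U <- matrix(stats::runif(n * m), n, m)
  V <- matrix(stats::runif(n * (m + 1L)), n, m + 1L)
  lower <- c(0, cut_points[-m])
  width <- cut_points - lower
  bin <- rep.int(m + 1L, n)
  t_event <- numeric(n)
  for (i in seq_len(n)) {
    hit <- which(U[i, ] < H[i, ])
    if (length(hit) > 0L) {
      b <- hit[1L]
      bin[i] <- b
      t_event[i] <- lower[b] + V[i, b] * width[b]
    } else {
      t_event[i] <- cut_points[m] + V[i, m + 1L] * mean(width)
    }
  }
  event <- rep.int(1L, n)
  time <- t_event
  horizon <- NA_real_
  cens <- rep(NA_real_, n)
  if (censoring_rate > 0) {
    f <- function(cc) mean(pmin(t_event, cc)) / cc - censoring_rate
    horizon <- stats::uniroot(f, c(1e-6, 50 * max(t_event)), tol = 1e-8)$root
    cens <- stats::runif(n, 0, horizon)
    censored <- cens < t_event
    time[censored] <- cens[censored]
    event[censored] <- 0L
  }
  list(time_days = time, event = event, event_bin = bin, hazard = H,
       censor_time = cens, censor_horizon = horizon)
}

# True cumulative incidence over the grid bins (+ beyond-horizon bin = 1).
true_cif <- function(hazard) {
  surv <- t(apply(1 - hazard, 1L, cumprod))
  cbind(1 - surv, 1)
}

#' Oracle time-dependent concordance from the true hazards
#'
#' Computes the time-dependent concordance index with the *true* cumulative
#' incidence (derived from the generating hazards) in place of model
#' predictions, using the same pair rules as [ctd()]. This is the
#' Bayes-optimal reference no predictor built from the observed data can
#' systematically exceed.
#'
#' @param hazard n x bins matrix of true per-bin hazards.
#' @param times,events observed outcomes.
#' @param cut_points the day grid that defined the bins.
#' @return concordance in `[0, 1]`.
#' @export
bayes_optimal_ctd <- function(hazard, times, events,
                              cut_points = default_cut_points()) {
  stopifnot(nrow(hazard) == length(times), length(times) == length(events))
  Fm <- true_cif(hazard)
  grid <- list(cut_points = cut_points, t_max = max(cut_points))
  bins <- vapply(times, discretize_time, 1L, grid = grid)
  ctd(cif_at_bins(Fm, bins), times, events)
}

#' Generate a full multimodal cohort with ground truth
#'
#' Clinical covariates, per-subject volumes whose lesion volume fraction
#' (standardized) enters the hazard with weight `beta_imaging`, and censored
#' discrete-time outcomes. Lesion fractions are drawn uniformly on
#' `[0.01, 0.15]` and standardized by the moments of that distribution.
#'
#' @param config a [synth_config()].
#' @param imaging generate volumes? (`FALSE` gives a tabular-only cohort and
#'   drops the imaging term from the hazard).
#' @return a `synth_cohort`: `clinical` (table incl. outcomes), `X` (encoded
#'   design), `volumes` (list or NULL), `ground_truth` (true risk, hazards,
#'   imaging feature), `config`.
#' @export
generate_cohort <- function(config, imaging = !is.null(config$volume_shape)) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  cl <- generate_clinical(n, config$beta_clinical, seed = config$seed)
  lp <- cl$lp
  volumes <- NULL
  frac <- rep(NA_real_, n)
  if (imaging) {
    set.seed(config$seed + 13L)
    target <- stats::runif(n, 0.01, 0.15)
    volumes <- vector("list", n)
    for (i in seq_len(n)) {
      volumes[[i]] <- generate_volume(target[i], shape = config$volume_shape,
                                      seed = config$seed + 1000L + i)
      frac[i] <- volumes[[i]]$lesion_fraction
    }
    # standardize by the design moments of U(0.01, 0.15)
    z <- (frac - 0.08) / (0.14 / sqrt(12))
    lp <- lp + config$beta_imaging * z
  }
  sv <- sample_survival(lp, cut_points = config$cut_points,
                        baseline_logit_hazard = config$baseline_logit_hazard,
                        censoring_rate = config$censoring_rate,
                        seed = config$seed + 7L)
  clinical <- cbind(cl$table, time_days = sv$time_days, event = sv$event)
  structure(list(clinical = clinical, X = cl$X, volumes = volumes,
                 ground_truth = list(true_risk = lp, true_hazard = sv$hazard,
                                     imaging_feature = frac,
                                     event_bin = sv$event_bin),
                 config = config),
            class = "synth_cohort")
}

#' Generate a tabular-only cohort with generic Gaussian covariates
#'
#' For parameter-recovery experiments: `p = length(betas)` standard-normal
#' covariates, linear predictor `X %*% betas`, discrete-time outcomes.
#'
#' @param n cohort size.
#' @param betas log-hazard ratios.
#' @param censoring_rate,cut_points,baseline_logit_hazard,seed see
#'   [sample_survival()].
#' @return list with `X`, `time_days`, `event`, `ground_truth`.
#' @export
generate_tabular_cohort <- function(n, betas = c(1, -1), censoring_rate = 0.3,
                                    cut_points = default_cut_points(),
                                    baseline_logit_hazard = default_baseline_logit_hazard(),
                                    seed = 1L) {
  set.seed(seed)
  p <- length(betas)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  lp <- drop(X %*% betas)
  sv <- sample_survival(lp, cut_points = cut_points,
                        baseline_logit_hazard = baseline_logit_hazard,
                        censoring_rate = censoring_rate, seed = seed + 7L)
  list(X = X, time_days = sv$time_days, event = sv$event,
       ground_truth = list(true_risk = lp, true_hazard = sv$hazard,
                           event_bin = sv$event_bin),
       cut_points = cut_points)
}

#' Write a cohort to disk (NIfTI volumes + CSV tables)
#'
#' One NIfTI file per channel per subject (`<id>_{t1,t1c,t2,flair}.nii.gz`),
#' `clinical.csv` and `ground_truth.csv`.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- c("t1", "t1c", "t2", "flair")
  if (!is.null(cohort$volumes)) {
    for (i in seq_along(cohort$volumes)) {
      id <- cohort$clinical$id[i]
      v <- cohort$volumes[[i]]
      for (ch in seq_len(dim(v$data)[1L])) {
        RNifti::writeNifti(v$data[ch, , , ],
                           file.path(dir, paste0(id, "_", suffix[ch], ".nii.gz")))
      }
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  gt <- data.frame(id = cohort$clinical$id,
                   true_risk = cohort$ground_truth$true_risk,
                   imaging_feature = cohort$ground_truth$imaging_feature)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
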