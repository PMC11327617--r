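# Experiment orchestration: stratified splitting, the two-stage workflow
# (pretrain -> freeze -> survival training), single-use test evaluation and
# the ablation harness.

#' Stratified train/validation/test split
#'
#' Stratification cells are event indicator x survival-time tertile;
#' allocation is proportional within each cell (largest remainder), with a
#' fix-up pass so the overall split sizes are exact. Cells with fewer than 3
#' members trigger a fallback to event-only stratification with a warning.
#'
#' @param times,events outcomes of all subjects.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @return list with `assignment` (factor `train`/`val`/`test`) and `audit`
#'   (per-split size, event fraction, median time).
#' @export
stratified_split <- function(times, events, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  n <- length(times)
  stopifnot(n >= 20L, abs(sum(fractions) - 1) < 1e-9, length(events) == n)
  set.seed(seed)
  splits <- c("train", "val", "test")
  # exact overall targets by largest remainder
  raw <- n * fractions
  tgt <- floor(raw)
  rem <- order(raw - tgt, decreasing = TRUE)
  for (k in seq_len(n - sum(tgt))) tgt[rem[k]] <- tgt[rem[k]] + 1L
  ter <- cut(times, breaks = stats::quantile(times, c(0, 1 / 3, 2 / 3, 1)),
             include.lowest = TRUE, labels = FALSE)
  cell <- interaction(events, ter, drop = TRUE)
  if (min(table(cell)) < 3L) {
    warning("sparse stratification cell; falling back to event-only stratification")
    cell <- factor(events)
  }
  assign <- character(n)
  for (cl in levels(cell)) {
    idx <- sample(which(cell == cl))
    m <- length(idx)
    craw <- m * fractions
    cnt <- floor(craw)
    crem <- order(craw - cnt, decreasing = TRUE)
    for (k in seq_len(m - sum(cnt))) cnt[crem[k]] <- cnt[crem[k]] + 1L
    assign[idx] <- rep(splits, cnt)
  }
  # fix-up pass to meet the exact overall sizes
  tot <- function() vapply(splits, function(s) sum(assign == s), 1L)
  repeat {
    tt <- tot()
    over <- which(tt > tgt); under <- which(tt < tgt)
    if (length(over) == 0L) break
    mv <- sample(which(assign == splits[over[1L]]), 1L)
    assign[mv] <- splits[under[1L]]
  }
  assign <- factor(assign, levels = splits)
  audit <- do.call(rbind, lapply(splits, function(s) {
    sel <- assign == s
    data.frame(split = s, n = sum(sel), event_frac = mean(events[sel]),
               median_time = stats::median(times[sel]))
  }))
  list(assignment = assign, audit = audit)
}

#' Experiment configuration
#'
#' Bundles cohort, split, pretraining and survival-training settings for
#' [run_experiment()].
#'
#' @param n_subjects cohort size.
#' @param modality `"multimodal"`, `"clinical"` or `"imaging"`.
#' @param volume_shape voxel extents of the synthetic volumes.
#' @param fractions train/val/test fractions.
#' @param seed_data,seed_model seeds for cohort/split and for model
#'   initialization/training.
#' @param synth named overrides for [synth_config()].
#' @param vit a [vit_config()].
#' @param pretrain list: `epochs`, `batch_size`, `lr`.
#' @param train list: `lr`, `batch_size`, `epochs`, `patience`,
#'   `lambda_rank`, `sigma`, `L_c`, `n_heads`, `hidden`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 200L,
                              modality = c("multimodal", "clinical", "imaging"),
                              volume_shape = c(32L, 32L, 32L),
                              fractions = c(0.70, 0.15, 0.15),
                              seed_data = 1L, seed_model = 1L,
                              synth = list(), vit = vit_config(),
                              pretrain = list(epochs = 8L, batch_size = 8L, lr = 1e-3),
                              train = list(lr = 1e-3, weight_decay = 1e-3,
                                           batch_size = 16L,
                                           epochs = 60L, patience = 10L,
                                           lambda_rank = 0.5, sigma = 0.1,
                                           d_model = 32L, L_c = 4L,
                                           n_heads = 4L, hidden = 32L)) {
  modality <- match.arg(modality)
  structure(list(n_subjects = n_subjects, modality = modality,
                 volume_shape = volume_shape, fractions = fractions,
                 seed_data = seed_data, seed_model = seed_model,
                 synth = synth, vit = vit, pretrain = pretrain, train = train),
            class = "experiment_config")
}

#' Metric report for one evaluation split
#'
#' Computes the time-dependent concordance, monthly Brier scores with
#' censoring weights, the integrated Brier score, and the log-rank test of
#' the dichotomized risk groups.
#'
#' @param pred output of [predict_survival()].
#' @param times,events outcomes of the evaluated subjects.
#' @param grid the model's `time_grid`.
#' @param threshold_months dichotomization threshold (training median).
#' @return list with `ctd`, `brier`, `ibs`, `logrank_chi2`, `logrank_p`,
#'   `groups`.
#' @export
metric_report <- function(pred, times, events, grid, threshold_months = 12) {
  bins <- vapply(times, discretize_time, 1L, grid = grid)
  nb <- ncol(pred$cif)
  ct <- ctd(cif_at_bins(pred$cif, pmin(bins, nb)), times, events)
  months <- seq_len(ncol(pred$monthly))
  cens_km <- km_estimator(times, 1L - events)
  bs <- vapply(months, function(m) {
    brier_score(pred$monthly[, m], times, events, m * grid$month_days, cens_km)
  }, 0)
  ibs <- integrated_brier(bs, months * grid$month_days)
  groups <- dichotomize(pred$monthly, threshold_months)
  if (nlevels(droplevels(groups)) == 2L) {
    lr <- logrank_test(groups, times, events)
  } else {
    lr <- list(chi2 = NA_real_, p = NA_real_)
  }
  list(ctd = ct, brier = bs, ibs = ibs, logrank_chi2 = lr$chi2,
       logrank_p = lr$p, groups = groups)
}

#' Evaluate the held-out test split exactly once
#'
#' The experiment carries a consumed flag; a second evaluation attempt is an
#' error, enforcing the test-set discipline.
#'
#' @param exp a `gliosurv_experiment`.
#' @return the test [metric_report()].
#' @export
evaluate_test <- function(exp) {
  stopifnot(inherits(exp, "gliosurv_experiment"))
  if (isTRUE(exp$guard$consumed)) {
    stop("test split already evaluated for this experiment")
  }
  exp$guard$consumed <- TRUE
  te <- which(exp$split$assignment == "test")
  pred <- predict_survival(
    exp$model,
    X = if (exp$config$modality != "imaging") exp$X[te, , drop = FALSE] else NULL,
    img_tokens = if (exp$config$modality != "clinical") exp$img_tokens[te] else NULL)
  metric_report(pred, exp$times[te], exp$events[te], exp$grid,
                threshold_months = exp$threshold_months)
}

#' Run the two-stage experiment end to end
#'
#' Generates (or accepts) a synthetic cohort, splits it, fits all
#' preprocessing statistics on the training split, pretrains and freezes the
#' image encoder (imaging modalities), trains the survival model with early
#' stopping on the validation likelihood, and evaluates the held-out test
#' split exactly once.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-generated `synth_cohort` (must match
#'   `config$modality`); generated from `config` when `NULL`.
#' @param encoder optional pretrained `vit_encoder` to reuse (skips
#'   pretraining).
#' @return a `gliosurv_experiment` with the trained model, reports and
#'   audit fields.
#' @export
run_experiment <- function(config, cohort = NULL, encoder = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  imaging <- config$modality != "clinical"
  if (is.null(cohort)) {
    sc_args <- utils::modifyList(
      list(n_subjects = config$n_subjects,
           volume_shape = if (imaging) config$volume_shape else NULL,
           seed = config$seed_data),
      config$synth)
    cohort <- generate_cohort(do.call(synth_config, sc_args))
  }
  times <- cohort$clinical$time_days
  events <- cohort$clinical$event
  split <- stratified_split(times, events, config$fractions, seed = config$seed_data)
  tr <- which(split$assignment == "train")
  va <- which(split$assignment == "val")
  # covariate encoding fitted on the training split only
  enc <- fit_covariate_encoding(cohort$clinical[tr, ])
  X <- encode_covariates(cohort$clinical, enc)
  grid <- build_time_grid(times[tr])
  img_tokens <- NULL
  if (imaging) {
    landmarks <- fit_histogram_landmarks(cohort$volumes[tr])
    vols <- lapply(cohort$volumes, function(v) {
      znorm_volume(histogram_standardize(v, landmarks))
    })
    if (is.null(encoder)) {
      encoder <- new_encoder(config$vit, config$volume_shape,
                             n_channels = dim(vols[[1L]]$data)[1L],
                             seed = config$seed_model)
      encoder <- pretrain_encoder(encoder, vols[tr],
                                  epochs = config$pretrain$epochs,
                                  batch_size = config$pretrain$batch_size,
                                  lr = config$pretrain$lr,
                                  seed = config$seed_model)
    }
    img_tokens <- lapply(vols, encode_volume, encoder = encoder)
  }
  km_tr <- km_estimator(times[tr], events[tr])
  med_idx <- which(km_tr$values < 0.5)
  threshold_months <- if (length(med_idx) > 0L) {
    km_tr$jump_times[med_idx[1L]] / DAYS_PER_MONTH
  } else {
    stats::median(times[tr]) / DAYS_PER_MONTH
  }
  tr_cfg <- config$train
  model <- train_survival_model(
    X = X, times = times, events = events, grid = grid,
    img_tokens = img_tokens, modality = config$modality,
    train_idx = tr, val_idx = va,
    lr = tr_cfg$lr, weight_decay = tr_cfg$weight_decay %||% 1e-3,
    batch_size = tr_cfg$batch_size, epochs = tr_cfg$epochs,
    patience = tr_cfg$patience, lambda_rank = tr_cfg$lambda_rank,
    sigma = tr_cfg$sigma, d_model = tr_cfg$d_model %||% 32L,
    L_c = tr_cfg$L_c, n_heads = tr_cfg$n_heads,
    hidden = tr_cfg$hidden, seed = config$seed_model)
  pred_val <- predict_survival(
    model, X = if (config$modality != "imaging") X[va, , drop = FALSE] else NULL,
    img_tokens = if (imaging) img_tokens[va] else NULL)
  val_report <- metric_report(pred_val, times[va], events[va], grid,
                              threshold_months)
  exp <- structure(list(config = config, split = split, grid = grid,
                        model = model, encoder = encoder, X = X,
                        img_tokens = img_tokens, times = times, events = events,
                        cohort = cohort, threshold_months = threshold_months,
                        split_hash = paste(as.integer(split$assignment),
                                           collapse = ""),
                        val_report = val_report,
                        guard = new.env(parent = emptyenv())),
                   class = "gliosurv_experiment")
  exp$test_report <- evaluate_test(exp)
  exp
}

#' Ablation harness over modalities or loss modes
#'
#' Re-runs the experiment per requested mode with identical data seed (hence
#' identical cohort and split, audited by hash) and reports test Ctd and IBS
#' per mode.
#'
#' @param config base [experiment_config()].
#' @param modes character vector: modalities (`"clinical"`, `"imaging"`,
#'   `"multimodal"`) or SSL loss modes (for `type = "loss_mode"`).
#' @param type what the modes vary.
#' @return data frame with one row per mode (`mode`, `ctd`, `ibs`,
#'   `split_hash`).
#' @export
ablation_suite <- function(config, modes, type = c("modality", "loss_mode")) {
  type <- match.arg(type)
  stopifnot(length(modes) >= 2L)
  # one shared cohort (with volumes when any mode needs them) so every mode
  # sees the identical data and split
  any_imaging <- type == "loss_mode" ||
    any(modes %in% c("imaging", "multimodal")) || config$modality != "clinical"
  sc_args <- utils::modifyList(
    list(n_subjects = config$n_subjects,
         volume_shape = if (any_imaging) config$volume_shape else NULL,
         seed = config$seed_data),
    config$synth)
  cohort <- generate_cohort(do.call(synth_config, sc_args))
  shared_encoder <- NULL
  rows <- lapply(modes, function(md) {
    cfg <- config
    if (type == "modality") {
      cfg$modality <- md
    } else {
      cfg$vit$loss_mode <- md
    }
    ex <- run_experiment(cfg, cohort = cohort,
                         encoder = if (type == "modality") shared_encoder)
    if (type == "modality" && cfg$modality != "clinical" &&
        is.null(shared_encoder)) {
      shared_encoder <<- ex$encoder
    }
    data.frame(mode = md, ctd = ex$test_report$ctd, ibs = ex$test_report$ibs,
               split_hash = ex$split_hash, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
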