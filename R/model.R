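# The trainable discrete-time survival model: clinical encoder,
# cross-attention fusion over frozen image encodings, attention pooling and
# the softmax survival head, trained with the likelihood + ranking loss.

surv_model_config <- function(modality, p_clin = NULL, d_model = 32L,
                              L_c = 4L, n_heads = 4L, hidden = 32L,
                              n_img_tok = NULL, d_img = NULL, n_cells = 6L) {
  stopifnot(modality %in% c("clinical", "imaging", "multimodal"))
  if (modality != "imaging" && is.null(p_clin)) stop("p_clin required")
  if (modality != "clinical" && (is.null(n_img_tok) || is.null(d_img))) {
    stop("n_img_tok and d_img required")
  }
  list(modality = modality, p_clin = p_clin, d_model = as.integer(d_model),
       L_c = as.integer(L_c), n_heads = as.integer(n_heads),
       hidden = as.integer(hidden), n_img_tok = n_img_tok, d_img = d_img,
       n_cells = as.integer(n_cells))
}

surv_param_init <- function(cfg) {
  d <- cfg$d_model
  params <- list()
  if (cfg$modality != "imaging") {
    params <- c(params,
                lin_params("ce.fc1", cfg$p_clin, cfg$hidden),
                lin_params("ce.fc2", cfg$hidden, cfg$L_c * d))
  }
  if (cfg$modality != "clinical") {
    # trainable projection of the frozen encoder tokens into the shared
    # fusion width, plus learned fusion-level positions
    params <- c(params,
                lin_params("iproj", cfg$d_img, d),
                stats::setNames(
      list(matrix(stats::rnorm(cfg$n_img_tok * d, sd = 0.02), cfg$n_img_tok, d)),
      "fpos"))
  }
  if (cfg$modality == "multimodal") {
    params <- c(params,
                ln_params("ca_img.lnq", d), ln_params("ca_img.lnkv", d),
                attn_params("ca_img.attn", d),
                ln_params("ca_clin.lnq", d), ln_params("ca_clin.lnkv", d),
                attn_params("ca_clin.attn", d))
  } else {
    params <- c(params, ln_params("sa.ln", d), attn_params("sa.attn", d))
  }
  if (cfg$modality != "imaging") {
    params <- c(params,
                ln_params("fin.lnq", d), ln_params("fin.lnkv", d),
                attn_params("fin.attn", d))
  }
  c(params,
    ln_params("pool.ln", d),
    stats::setNames(list(matrix(stats::rnorm(d, sd = 0.2), 1L, d),
                         matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d),
                         matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)),
                    c("pool.q", "pool.Wk", "pool.Wv")),
    lin_params("head.fc1", d, d),
    lin_params("head.fc2", d, cfg$n_cells))
}

# One subject's forward pass to the logit row (1 x n_cells).
surv_forward <- function(tape, P, cfg, x = NULL, img = NULL) {
  d <- cfg$d_model
  clin0 <- NULL
  if (cfg$modality != "imaging") {
    xi <- ad_const(tape, matrix(x, 1L))
    h <- ad_relu(tape, ad_linear(tape, P, "ce.fc1", xi))
    o <- ad_linear(tape, P, "ce.fc2", h)
    # reshape the 1 x (L_c * d) row into L_c tokens (row-major)
    rows <- lapply(seq_len(cfg$L_c), function(k) {
      ad_cols(tape, o, ((k - 1L) * d + 1L):(k * d))
    })
    clin0 <- ad_rbind(tape, rows)
  }
  img0 <- NULL
  if (cfg$modality != "clinical") {
    img0 <- ad_add(tape, ad_linear(tape, P, "iproj", ad_const(tape, img)),
                   P("fpos"))
  }
  if (cfg$modality == "multimodal") {
    iq <- ad_ln(tape, P, "ca_img.lnq", img0)
    ikv <- ad_ln(tape, P, "ca_img.lnkv", clin0)
    img1 <- ad_add(tape, img0, ad_mha(tape, P, "ca_img.attn", iq, ikv, cfg$n_heads))
    cq <- ad_ln(tape, P, "ca_clin.lnq", clin0)
    ckv <- ad_ln(tape, P, "ca_clin.lnkv", img0)
    clin1 <- ad_add(tape, clin0, ad_mha(tape, P, "ca_clin.attn", cq, ckv, cfg$n_heads))
    kv <- ad_rbind(tape, list(img1, clin1))
    fq <- ad_ln(tape, P, "fin.lnq", clin0)
    fkv <- ad_ln(tape, P, "fin.lnkv", kv)
    fused <- ad_add(tape, clin0, ad_mha(tape, P, "fin.attn", fq, fkv, cfg$n_heads))
  } else if (cfg$modality == "clinical") {
    sq <- ad_ln(tape, P, "sa.ln", clin0)
    clin1 <- ad_add(tape, clin0, ad_mha(tape, P, "sa.attn", sq, sq, cfg$n_heads))
    fq <- ad_ln(tape, P, "fin.lnq", clin0)
    fkv <- ad_ln(tape, P, "fin.lnkv", clin1)
    fused <- ad_add(tape, clin0, ad_mha(tape, P, "fin.attn", fq, fkv, cfg$n_heads))
  } else {  # imaging
    sq <- ad_ln(tape, P, "sa.ln", img0)
    fused <- ad_add(tape, img0, ad_mha(tape, P, "sa.attn", sq, sq, cfg$n_heads))
  }
  pooled_in <- ad_ln(tape, P, "pool.ln", fused)
  K <- ad_matmul(tape, pooled_in, P("pool.Wk"))
  V <- ad_matmul(tape, pooled_in, P("pool.Wv"))
  sc <- ad_scale(tape, ad_matmul(tape, P("pool.q"), ad_transpose(tape, K)),
                 1 / sqrt(d))
  pooled <- ad_matmul(tape, ad_rowsoftmax(tape, sc), V)
  h2 <- ad_relu(tape, ad_linear(tape, P, "head.fc1", pooled))
  ad_linear(tape, P, "head.fc2", h2)
}

# Likelihood mask: event subjects pick their bin's cell; censored subjects
# the mass strictly beyond their bin (the beyond cell for bin >= n_bins + 1).
likelihood_mask <- function(bins, events, n_cells) {
  n <- length(bins)
  M <- matrix(0, n, n_cells)
  for (i in seq_len(n)) {
    if (events[i] == 1L) {
      M[i, min(bins[i], n_cells)] <- 1
    } else if (bins[i] >= n_cells) {
      M[i, n_cells] <- 1
    } else {
      M[i, (bins[i] + 1L):n_cells] <- 1
    }
  }
  M
}

# Batched training loss on the tape. Returns the total-loss node and the
# numeric component values.
surv_batch_graph <- function(tape, P, cfg, X, img_list, bins, events,
                             lambda_rank = 0.5, sigma = 0.1) {
  n <- length(bins)
  logit_nodes <- vector("list", n)
  for (i in seq_len(n)) {
    logit_nodes[[i]] <- surv_forward(
      tape, P, cfg,
      x = if (cfg$modality != "imaging") X[i, ] else NULL,
      img = if (cfg$modality != "clinical") img_list[[i]] else NULL)
  }
  Y <- ad_rowsoftmax(tape, ad_rbind(tape, logit_nodes))
  nc <- cfg$n_cells
  M <- likelihood_mask(bins, events, nc)
  psel <- ad_rowsums(tape, ad_mul(tape, Y, ad_const(tape, M)))
  L1 <- ad_scale(tape, ad_mean_all(tape, ad_log_clamped(tape, psel)), -1)
  # ranking term over acceptable pairs
  nb <- nc - 1L
  Lmat <- matrix(0, nc, nb)
  for (m in seq_len(nb)) Lmat[seq_len(m), m] <- 1
  E <- matrix(0, n, nb)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (events[i] == 1L && bins[i] <= nb) {
      E[i, bins[i]] <- 1
      A[i, bins > bins[i]] <- 1
    }
  }
  nA <- sum(A)
  if (nA > 0 && lambda_rank > 0) {
    Cum <- ad_matmul(tape, Y, ad_const(tape, Lmat))
    g <- ad_rowsums(tape, ad_mul(tape, Cum, ad_const(tape, E)))
    M2 <- ad_matmul(tape, ad_const(tape, E), ad_transpose(tape, Cum))
    Eta <- ad_exp(tape, ad_scale(tape, ad_colvec_minus(tape, g, M2), -1 / sigma))
    L2 <- ad_scale(tape, ad_sum_all(tape, ad_mul(tape, Eta, ad_const(tape, A))),
                   1 / nA)
    total <- ad_add(tape, L1, ad_scale(tape, L2, lambda_rank))
    l2v <- L2$val[1L]
  } else {
    total <- L1
    l2v <- 0
  }
  list(total = total, L1 = L1$val[1L], L2 = l2v, y = Y$val)
}

#' Train the discrete-time survival model
#'
#' Minibatch Adam (with decoupled weight decay) on the combined likelihood +
#' ranking loss. Early stopping monitors validation concordance with a small
#' likelihood penalty as tie-breaker, and the best-validation parameters are
#' kept. Image encodings are consumed frozen: they enter the tape as
#' constants, so no gradient can reach the encoder.
#'
#' @param X encoded covariate matrix (subjects x p); ignored for
#'   `modality = "imaging"`.
#' @param times,events observed outcomes (days, 0/1).
#' @param grid a `time_grid` built from the *training* times.
#' @param img_tokens list of frozen token matrices (subjects), for
#'   `"imaging"`/`"multimodal"`.
#' @param modality `"clinical"`, `"imaging"` or `"multimodal"`.
#' @param train_idx indices used for gradient updates; defaults to all
#'   subjects not in `val_idx`.
#' @param val_idx indices of the validation subjects; by default a random
#'   20 percent event-stratified carve-out.
#' @param d_model shared fusion embedding width; frozen image tokens are
#'   projected into it by a trainable linear layer.
#' @param weight_decay decoupled weight decay on the weight matrices.
#' @param L_c clinical token sequence length.
#' @param n_heads heads at every attention site.
#' @param hidden clinical encoder hidden width.
#' @param lr,batch_size,epochs,patience optimization settings; stopping is
#'   never triggered before `min_epochs`.
#' @param min_epochs minimum number of epochs before early stopping can fire.
#' @param restore_best return the best-validation parameters (`TRUE`) or the
#'   final-epoch parameters.
#' @param lambda_rank,sigma ranking-loss constants.
#' @param seed integer seed (initialization + shuffling).
#' @return a `gliosurv_model` with `params`, `cfg`, `grid` and a training
#'   `log`.
#' @export
train_survival_model <- function(X, times, events, grid, img_tokens = NULL,
                                 modality = c("clinical", "imaging", "multimodal"),
                                 train_idx = NULL, val_idx = NULL,
                                 d_model = 32L, L_c = 4L,
                                 n_heads = 4L, hidden = 32L, lr = 1e-3,
                                 weight_decay = 1e-3,
                                 batch_size = 16L, epochs = 60L, patience = 10L,
                                 min_epochs = 15L, restore_best = TRUE,
                                 lambda_rank = 0.5, sigma = 0.1, seed = 1L) {
  modality <- match.arg(modality)
  n <- length(times)
  if (modality != "clinical") stopifnot(length(img_tokens) == n)
  cfg <- surv_model_config(
    modality,
    p_clin = if (modality != "imaging") ncol(X) else NULL,
    d_model = d_model, L_c = L_c, n_heads = n_heads, hidden = hidden,
    n_img_tok = if (modality != "clinical") nrow(img_tokens[[1L]]) else NULL,
    d_img = if (modality != "clinical") ncol(img_tokens[[1L]]) else NULL)
  set.seed(seed)
  if (is.null(val_idx)) {
    val_idx <- unlist(lapply(split(seq_len(n), events), function(ix) {
      sample(ix, max(1L, round(0.2 * length(ix))))
    }), use.names = FALSE)
  }
  tr_idx <- if (is.null(train_idx)) setdiff(seq_len(n), val_idx) else train_idx
  bins <- vapply(times, discretize_time, 1L, grid = grid)
  params <- surv_param_init(cfg)
  opt <- adam_new(params, lr = lr)
  best <- list(score = -Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_l1 = numeric(), val_ctd = numeric())
  wait <- 0L
  nb <- cfg$n_cells - 1L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    tot <- c()
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next
      tape <- new_tape()
      P <- param_binder(tape, params)
      g <- surv_batch_graph(tape, P, cfg,
                            X = if (modality != "imaging") X[idx, , drop = FALSE] else NULL,
                            img_list = if (modality != "clinical") img_tokens[idx] else NULL,
                            bins = bins[idx], events = events[idx],
                            lambda_rank = lambda_rank, sigma = sigma)
      ad_backward(tape, g$total)
      st <- adam_step(opt, params, binder_grads(P, params),
                      weight_decay = weight_decay)
      opt <- st$opt; params <- st$params
      tot <- c(tot, g$total$val[1L])
    }
    model_ep <- structure(list(params = params, cfg = cfg, grid = grid),
                          class = "gliosurv_model")
    pv <- predict_survival(model_ep,
                           X = if (modality != "imaging") X[val_idx, , drop = FALSE] else NULL,
                           img_tokens = if (modality != "clinical") img_tokens[val_idx] else NULL)
    val_l1 <- likelihood_loss(pv$y, bins[val_idx], events[val_idx])
    val_ctd <- tryCatch(
      ctd(cif_at_bins(pv$cif, pmin(bins[val_idx], nb)),
          times[val_idx], events[val_idx]),
      error = function(e) NA_real_)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tot),
                                 val_l1 = val_l1, val_ctd = val_ctd))
    # model selection on validation concordance (likelihood as tie-breaker
    # through the penalty term): at desk-scale cohort sizes the validation
    # likelihood saturates within a few epochs while discrimination is still
    # improving, so concordance is the stopping signal that matters
    score <- if (is.na(val_ctd)) -val_l1 else val_ctd - 0.01 * val_l1
    if (score > best$score + 1e-6) {
      best <- list(score = score, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience && ep >= min_epochs) break
    }
  }
  if (!restore_best) best <- list(params = params, epoch = ep)
  structure(list(params = best$params, cfg = cfg, grid = grid, log = log,
                 best_epoch = best$epoch, val_idx = val_idx,
                 lambda_rank = lambda_rank, sigma = sigma, seed = seed),
            class = "gliosurv_model")
}

#' Predict individual survival from a trained model
#'
#' @param model a `gliosurv_model`.
#' @param X encoded covariates (subjects x p); `NULL` for imaging-only.
#' @param img_tokens list of frozen image token matrices; `NULL` for
#'   clinical-only.
#' @return list with `y` (cell probabilities), `cif`, `grid_surv` (S at the
#'   cut points) and `monthly` (linearly interpolated monthly S).
#' @export
predict_survival <- function(model, X = NULL, img_tokens = NULL) {
  cfg <- model$cfg
  n <- if (!is.null(X)) nrow(X) else length(img_tokens)
  logits <- matrix(0, n, cfg$n_cells)
  for (i in seq_len(n)) {
    tape <- new_tape()
    P <- param_binder(tape, model$params, trainable = FALSE)
    logits[i, ] <- surv_forward(
      tape, P, cfg,
      x = if (cfg$modality != "imaging") X[i, ] else NULL,
      img = if (cfg$modality != "clinical") img_tokens[[i]] else NULL)$val
  }
  y <- softmax_probabilities(logits)
  gs <- survival_function(y)
  list(y = y, cif = cif(y), grid_surv = gs,
       monthly = interpolate_monthly(gs, model$grid))
}
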