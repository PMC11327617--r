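# Self-supervised pretraining of the image encoder: two augmented views per
# volume feed a context-restoration (reconstruction) task and an NT-Xent
# contrastive task; the combined objective follows the configured loss mode.

#' Augment a volume with random patch swapping and cutout
#'
#' Patch swapping exchanges the contents of disjoint same-size blocks on the
#' block grid; cutout zeroes randomly placed boxes. All random choices are
#' recorded in an alteration log so a view can be replayed (swapping the same
#' pair twice restores the original).
#'
#' @param x a `volume_stack` or 4D array (channels, X, Y, Z).
#' @param n_swaps number of disjoint block pairs to swap.
#' @param cutout list with `count` (number of boxes) and `max_extent`
#'   (integer triple, maximum box size per axis).
#' @param block_size block grid used for swapping; kept equal to the ViT
#'   patch size by default so augmentation aligns with tokenization.
#' @return list with `data` (augmented array) and `log` (the alteration log).
#' @export
augment_view <- function(x, n_swaps = 4L,
                         cutout = list(count = 2L, max_extent = c(8L, 8L, 8L)),
                         block_size = c(8L, 8L, 8L)) {
  arr <- if (inherits(x, "volume_stack")) x$data else x
  d <- dim(arr)
  stopifnot(length(d) == 4L, n_swaps >= 0L, cutout$count >= 0L)
  bs <- as.integer(block_size)
  nb <- d[2:4] %/% bs
  n_blocks <- prod(nb)
  log <- list(swaps = list(), cutouts = list())
  if (n_swaps > 0L) {
    if (2L * n_swaps > n_blocks) {
      stop("cannot sample ", 2L * n_swaps, " disjoint blocks from a grid of ",
           n_blocks)
    }
    picked <- sample.int(n_blocks, 2L * n_swaps)
    for (s in seq_len(n_swaps)) {
      log$swaps[[s]] <- c(picked[2L * s - 1L], picked[2L * s])
    }
    arr <- apply_block_swaps(arr, log$swaps, bs)
  }
  if (cutout$count > 0L) {
    mx <- pmin(as.integer(cutout$max_extent), d[2:4])
    if (any(mx < 1L)) stop("cutout extent must be at least 1 voxel per axis")
    for (ci in seq_len(cutout$count)) {
      ext <- vapply(mx, function(m) sample.int(m, 1L), 1L)
      lo <- vapply(seq_len(3L), function(a) sample.int(d[a + 1L] - ext[a] + 1L, 1L), 1L)
      hi <- lo + ext - 1L
      arr[, lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- 0
      log$cutouts[[ci]] <- list(lo = lo, hi = hi)
    }
  }
  list(data = arr, log = log)
}

block_range <- function(block_id, nb, bs) {
  b0 <- block_id - 1L
  bx <- b0 %% nb[1L]
  by <- (b0 %/% nb[1L]) %% nb[2L]
  bz <- b0 %/% (nb[1L] * nb[2L])
  list(x = (bx * bs[1L] + 1L):((bx + 1L) * bs[1L]),
       y = (by * bs[2L] + 1L):((by + 1L) * bs[2L]),
       z = (bz * bs[3L] + 1L):((bz + 1L) * bs[3L]))
}

#' @rdname augment_view
#' @param arr 4D array.
#' @param swaps list of length-2 block-id vectors (as in the alteration log).
#' @export
apply_block_swaps <- function(arr, swaps, block_size) {
  bs <- as.integer(block_size)
  nb <- dim(arr)[2:4] %/% bs
  for (pair in swaps) {
    r1 <- block_range(pair[1L], nb, bs)
    r2 <- block_range(pair[2L], nb, bs)
    tmp <- arr[, r1$x, r1$y, r1$z]
    arr[, r1$x, r1$y, r1$z] <- arr[, r2$x, r2$y, r2$z]
    arr[, r2$x, r2$y, r2$z] <- tmp
  }
  arr
}

#' Context-restoration reconstruction loss
#'
#' Mean absolute voxel error between a decoded volume and the original,
#' over the full volume and all channels.
#'
#' @param decoded,original `volume_stack`s or arrays of identical shape.
#' @return nonnegative scalar.
#' @export
reconstruction_loss <- function(decoded, original) {
  a <- if (inherits(decoded, "volume_stack")) decoded$data else decoded
  b <- if (inherits(original, "volume_stack")) original$data else original
  if (!identical(dim(a), dim(b))) stop("shape mismatch between decoded and original")
  mean(abs(a - b))
}

#' NT-Xent contrastive loss over paired views
#'
#' Rows `i` and `i + N` of `z` are the two views of subject `i`. For each of
#' the `2N` anchors the loss is `-log exp(s_pos / tau) / sum_k exp(s_k / tau)`
#' over all other rows, with cosine similarities `s`. Under embedding
#' collapse (all rows equal) the value is exactly `log(2N - 1)`.
#'
#' @param z matrix of `2N` projected view embeddings (N >= 2).
#' @param tau positive temperature.
#' @return nonnegative scalar.
#' @export
contrastive_loss <- function(z, tau = 0.1) {
  n2 <- nrow(z)
  stopifnot(n2 %% 2L == 0L, n2 >= 4L, tau > 0)
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero-norm embedding row")
  zn <- z / nrm
  S <- (zn %*% t(zn)) / tau
  diag(S) <- -Inf
  n <- n2 %/% 2L
  pos <- c(seq_len(n) + n, seq_len(n))
  mx <- apply(S, 1L, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  mean(lse - S[cbind(seq_len(n2), pos)])
}

#' Combine the self-supervised objectives
#'
#' @param rec,con nonnegative reconstruction and contrastive loss values.
#' @param mode one of `"additive"` (`rec + lambda * con`),
#'   `"product_regularized"` (`rec + lambda * con * rec`),
#'   `"contrastive_only"`, `"reconstruction_only"`.
#' @param lambda_con nonnegative weight.
#' @return scalar combined loss.
#' @export
combined_ssl_loss <- function(rec, con, mode = "product_regularized",
                              lambda_con = 1) {
  stopifnot(rec >= 0, con >= 0, lambda_con >= 0)
  switch(mode,
         additive = rec + lambda_con * con,
         product_regularized = rec + lambda_con * con * rec,
         contrastive_only = con,
         reconstruction_only = rec,
         stop("unknown loss mode: ", mode))
}

# Batched tape for one pretraining step. Returns loss nodes.
ssl_batch_graph <- function(tape, P, cfg, orig_tokens, view_tokens) {
  n <- length(orig_tokens)
  n_tok <- nrow(orig_tokens[[1L]])
  pool_row <- matrix(1 / n_tok, 1L, n_tok)
  rec_nodes <- vector("list", 2L * n)
  proj_nodes <- vector("list", 2L * n)
  for (v in 1:2) for (i in seq_len(n)) {
    slot <- (v - 1L) * n + i
    tok <- ad_const(tape, view_tokens[[v]][[i]])
    reps <- vit_forward(tape, P, cfg, tok)
    dec <- ad_linear(tape, P, "recon", reps)
    rec_nodes[[slot]] <- ad_mean_all(
      tape, ad_abs(tape, ad_sub(tape, dec, ad_const(tape, orig_tokens[[i]]))))
    pooled <- ad_matmul(tape, ad_const(tape, pool_row), reps)
    proj_nodes[[slot]] <- ad_linear(
      tape, P, "proj.fc2", ad_gelu(tape, ad_linear(tape, P, "proj.fc1", pooled)))
  }
  rec <- ad_mean_all(tape, ad_rbind(tape, rec_nodes))
  z <- ad_l2normalize_rows(tape, ad_rbind(tape, proj_nodes))
  S <- ad_scale(tape, ad_matmul(tape, z, ad_transpose(tape, z)), 1 / cfg$temperature)
  n2 <- 2L * n
  S <- ad_add(tape, S, ad_const(tape, diag(-1e9, n2)))
  lse <- ad_rowlogsumexp(tape, S)
  posmask <- matrix(0, n2, n2)
  posmask[cbind(seq_len(n2), c(seq_len(n) + n, seq_len(n)))] <- 1
  posv <- ad_rowsums(tape, ad_mul(tape, S, ad_const(tape, posmask)))
  con <- ad_mean_all(tape, ad_sub(tape, lse, posv))
  total <- switch(cfg$loss_mode,
    additive = ad_add(tape, rec, ad_scale(tape, con, cfg$lambda_con)),
    product_regularized = ad_add(tape, rec,
                                 ad_scale(tape, ad_mul(tape, con, rec), cfg$lambda_con)),
    contrastive_only = con,
    reconstruction_only = rec)
  list(total = total, rec = rec$val[1L], con = con$val[1L])
}

#' Pretrain the encoder with the two proxy tasks
#'
#' Each volume is augmented twice per epoch (patch swapping + cutout); both
#' views are encoded, decoded back to voxel space for the restoration loss,
#' and pooled/projected for the contrastive loss.
#'
#' @param encoder an untrained (or partially trained) `vit_encoder`.
#' @param volumes list of `volume_stack`s or 4D arrays matching the encoder
#'   geometry.
#' @param epochs,batch_size,lr optimization settings.
#' @param n_swaps,cutout augmentation settings, see [augment_view()].
#' @param seed integer; controls shuffling, augmentation and optimization.
#' @return the encoder with updated parameters, `trained = TRUE`, and a
#'   per-epoch training log (`epoch`, `rec`, `con`).
#' @export
pretrain_encoder <- function(encoder, volumes, epochs = 20L, batch_size = 8L,
                             lr = 1e-3, n_swaps = 4L,
                             cutout = list(count = 2L, max_extent = c(8L, 8L, 8L)),
                             seed = 1L) {
  stopifnot(inherits(encoder, "vit_encoder"), length(volumes) >= 2L)
  cfg <- encoder$cfg
  arrs <- lapply(volumes, function(v) if (inherits(v, "volume_stack")) v$data else v)
  orig_tokens <- lapply(arrs, patchify, patch_size = cfg$patch_size)
  params <- encoder$params
  opt <- adam_new(params, lr = lr)
  set.seed(seed)
  log <- data.frame(epoch = integer(), rec = numeric(), con = numeric())
  n <- length(arrs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    recs <- cons <- c()
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      if (length(idx) < 2L) next  # contrastive loss needs at least 2 subjects
      views <- list(vector("list", length(idx)), vector("list", length(idx)))
      for (j in seq_along(idx)) for (v in 1:2) {
        aug <- augment_view(arrs[[idx[j]]], n_swaps = n_swaps, cutout = cutout,
                            block_size = cfg$patch_size)
        views[[v]][[j]] <- patchify(aug$data, cfg$patch_size)
      }
      tape <- new_tape()
      P <- param_binder(tape, params)
      g <- ssl_batch_graph(tape, P, cfg, orig_tokens[idx], views)
      ad_backward(tape, g$total)
      st <- adam_step(opt, params, binder_grads(P, params))
      opt <- st$opt; params <- st$params
      recs <- c(recs, g$rec); cons <- c(cons, g$con)
    }
    log <- rbind(log, data.frame(epoch = ep, rec = mean(recs), con = mean(cons)))
  }
  encoder$params <- params
  encoder$trained <- TRUE
  encoder$log <- log
  encoder
}

#' Linear probe of the pooled encoder embedding
#'
#' Regresses a per-volume scalar target (e.g. lesion volume fraction) on the
#' mean-pooled frozen token embedding with a lightly ridge-stabilized linear
#' readout, and reports held-out R-squared.
#'
#' @param encoder a `vit_encoder` (trained or, with `allow_random_init`,
#'   randomly initialized).
#' @param volumes list of volumes; `target` numeric vector of equal length.
#' @param train_frac fraction used to fit the readout.
#' @param ridge ridge penalty on the (standardized) coefficients.
#' @param seed split seed.
#' @param allow_random_init passed to [encode_volume()].
#' @return list with `r2` (held-out), `r2_train`.
#' @export
linear_probe_r2 <- function(encoder, volumes, target, train_frac = 2 / 3,
                            ridge = 1e-2, seed = 1L, allow_random_init = FALSE) {
  stopifnot(length(volumes) == length(target))
  emb <- t(vapply(volumes, function(v) {
    colMeans(encode_volume(encoder, v, allow_random_init = allow_random_init))
  }, numeric(encoder$cfg$embed_dim)))
  set.seed(seed)
  n <- nrow(emb)
  tr <- sample.int(n, round(train_frac * n))
  mu <- colMeans(emb[tr, , drop = FALSE])
  sdv <- apply(emb[tr, , drop = FALSE], 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  xs <- sweep(sweep(emb, 2L, mu), 2L, sdv, "/")
  ytr <- target[tr]
  xtr <- xs[tr, , drop = FALSE]
  beta <- solve(crossprod(xtr) + diag(ridge, ncol(xs)),
                crossprod(xtr, ytr - mean(ytr)))
  pred <- function(X) drop(X %*% beta) + mean(ytr)
  te <- setdiff(seq_len(n), tr)
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  list(r2 = r2(target[te], pred(xs[te, , drop = FALSE])),
       r2_train = r2(ytr, pred(xtr)))
}
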