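# Cross-attention fusion of imaging and clinical token sequences.
#
# The exported functions here are plain-matrix forward implementations of
# the attention operations (convenient for inspection and testing); the
# trainable survival model in model.R builds the same computations on the
# autodiff tape, and a consistency test keeps the two in lockstep.

softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

#' Cross-attention between two token sequences
#'
#' Computes `softmax(Q_alpha K_beta' / sqrt(d_k)) V_beta` with queries
#' projected from `alpha` and keys/values from `beta`, yielding an enriched
#' representation of `alpha`. With several heads, column blocks of the
#' projections act as heads and their outputs are concatenated (and passed
#' through the output projection `Wo` when present).
#'
#' @param alpha,beta token sequences (rows are tokens, shared embedding dim).
#' @param params list with `Wq`, `Wk`, `Wv` (square projection matrices),
#'   optional biases `bq`, `bk`, `bv`, optional `Wo`/`bo`, and `n_heads`
#'   (default 1).
#' @return enriched `alpha` (same number of rows); the per-head attention
#'   weight matrices (rows summing to 1) are attached as attribute `"attn"`.
#' @export
cross_attention <- function(alpha, beta, params) {
  nh <- params$n_heads %||% 1L
  d <- ncol(params$Wq)
  if (d %% nh != 0L) stop("embedding dim not divisible by n_heads")
  dk <- d %/% nh
  if (dk <= 0L) stop("key dimension must be positive")
  addb <- function(m, b) if (is.null(b)) m else sweep(m, 2L, as.numeric(b), "+")
  Q <- addb(alpha %*% params$Wq, params$bq)
  K <- addb(beta %*% params$Wk, params$bk)
  V <- addb(beta %*% params$Wv, params$bv)
  out <- matrix(0, nrow(alpha), d)
  attn <- vector("list", nh)
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- softmax_rows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dk))
    attn[[h]] <- A
    out[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  if (!is.null(params$Wo)) out <- addb(out %*% params$Wo, params$bo)
  attr(out, "attn") <- attn
  out
}

#' Self-attention variant (clinical-only configuration)
#'
#' Identical machinery with `alpha = beta`, enabling the nonimaging-only
#' model.
#'
#' @inheritParams cross_attention
#' @param x token sequence.
#' @export
self_attention_variant <- function(x, params) {
  cross_attention(x, x, params)
}

#' Bidirectional cross-attention fusion
#'
#' The cross-attention is applied twice with independent parameter sets: once
#' with the image sequence as query (enriched by the clinical sequence) and
#' once the other way around.
#'
#' @param img_seq,clin_seq token sequences sharing the embedding dim.
#' @param params list with elements `img` and `clin`, each a parameter list
#'   for [cross_attention()].
#' @return list with `img_hat` and `clin_hat`.
#' @export
bidirectional_fusion <- function(img_seq, clin_seq, params) {
  stopifnot(nrow(img_seq) >= 1L, nrow(clin_seq) >= 1L)
  list(img_hat = cross_attention(img_seq, clin_seq, params$img),
       clin_hat = cross_attention(clin_seq, img_seq, params$clin))
}

#' Final attention over the concatenated sequences
#'
#' The enriched sequences are concatenated along the sequence axis and serve
#' as keys and values; the clinical data projection serves as query, so the
#' output has one row per clinical token.
#'
#' @param img_hat,clin_hat enriched sequences from [bidirectional_fusion()].
#' @param clin_proj the clinical projection used as the query sequence.
#' @param params [cross_attention()] parameter list.
#' @return fused sequence of `nrow(clin_proj)` tokens.
#' @export
final_attention <- function(img_hat, clin_hat, clin_proj, params) {
  cross_attention(clin_proj, rbind(img_hat, clin_hat), params)
}

#' Attention pooling of a token sequence
#'
#' A learned query vector attends over the sequence:
#' `out = sum_i softmax(q . k_i / sqrt(d_k)) v_i`, a convex combination of
#' the value rows.
#'
#' @param seq token sequence (nonempty).
#' @param params list with `q` (1 x d learned query), `Wk`, `Wv`.
#' @return pooled 1 x d vector; attention weights as attribute `"attn"`.
#' @export
attention_pool <- function(seq, params) {
  if (is.null(dim(seq)) || nrow(seq) < 1L) stop("empty sequence")
  d <- ncol(params$Wk)
  K <- seq %*% params$Wk
  V <- seq %*% params$Wv
  A <- softmax_rows(matrix(params$q, 1L) %*% t(K) / sqrt(d))
  out <- A %*% V
  attr(out, "attn") <- A
  out
}

#' Clinical covariate encoder
#'
#' A small fully connected stack mapping the encoded covariate vector to a
#' short token sequence (`L_c` tokens of the shared embedding dim).
#'
#' @param x encoded covariate row vector.
#' @param params list with `W1`, `b1`, `W2`, `b2`.
#' @param L_c number of clinical tokens.
#' @return `L_c x d` token sequence.
#' @export
clinical_encoder <- function(x, params, L_c = 4L) {
  x <- matrix(x, 1L)
  if (any(!is.finite(x))) stop("non-finite covariate input")
  h <- pmax(sweep(x %*% params$W1, 2L, as.numeric(params$b1), "+"), 0)
  o <- sweep(h %*% params$W2, 2L, as.numeric(params$b2), "+")
  matrix(o, nrow = L_c, byrow = TRUE)
}

#' Survival logits from the pooled representation
#'
#' Two fully connected layers with a rectifier between; the final width is
#' `n_bins + 1` (the extra beyond-horizon cell keeps `S(t_max) > 0`
#' representable).
#'
#' @param pooled 1 x d pooled vector.
#' @param params list with `W1`, `b1`, `W2`, `b2`.
#' @return logit row vector.
#' @export
predict_logits <- function(pooled, params) {
  pooled <- matrix(pooled, 1L)
  if (any(!is.finite(pooled))) stop("non-finite pooled input")
  h <- pmax(sweep(pooled %*% params$W1, 2L, as.numeric(params$b1), "+"), 0)
  sweep(h %*% params$W2, 2L, as.numeric(params$b2), "+")
}
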