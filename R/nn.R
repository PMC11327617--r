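# Layer constructors and the optimizer used by every trainable component.
# Parameters live in flat named lists of matrices ("prefix.name" keys), so a
# whole model is one list that Adam can walk generically.

init_linear <- function(d_in, d_out) {
  list(
    W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / (d_in + d_out))), d_in, d_out),
    b = matrix(0, 1L, d_out)
  )
}

lin_params <- function(prefix, d_in, d_out) {
  p <- init_linear(d_in, d_out)
  stats::setNames(list(p$W, p$b), paste0(prefix, c(".W", ".b")))
}

ln_params <- function(prefix, d) {
  stats::setNames(list(matrix(1, 1L, d), matrix(0, 1L, d)),
                  paste0(prefix, c(".g", ".b")))
}

# Attention site: queries projected from one sequence, keys/values from the
# (possibly different) other sequence, concat-of-heads then output projection.
attn_params <- function(prefix, d) {
  c(lin_params(paste0(prefix, ".q"), d, d),
    lin_params(paste0(prefix, ".k"), d, d),
    lin_params(paste0(prefix, ".v"), d, d),
    lin_params(paste0(prefix, ".o"), d, d))
}

mlp_params <- function(prefix, d, hidden) {
  c(lin_params(paste0(prefix, ".fc1"), d, hidden),
    lin_params(paste0(prefix, ".fc2"), hidden, d))
}

# Memoizing binder: P("name") returns the tape node for params[["name"]],
# creating it (as param or constant, depending on `trainable`) on first use.
param_binder <- function(tape, params, trainable = TRUE) {
  memo <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(memo[[name]])) return(memo[[name]])
    val <- params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- if (trainable) ad_param(tape, val) else ad_const(tape, val)
    memo[[name]] <- nd
    nd
  }
}

binder_grads <- function(binder, params) {
  memo <- environment(binder)$memo
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    nd <- memo[[nm]]
    out[[nm]] <- if (is.null(nd) || is.null(nd$grad)) {
      matrix(0, nrow(params[[nm]]), ncol(params[[nm]]))
    } else {
      nd$grad
    }
  }
  out
}

ad_linear <- function(tape, P, prefix, x) {
  ad_add_rowvec(tape, ad_matmul(tape, x, P(paste0(prefix, ".W"))),
                P(paste0(prefix, ".b")))
}

ad_ln <- function(tape, P, prefix, x) {
  ad_layernorm(tape, x, P(paste0(prefix, ".g")), P(paste0(prefix, ".b")))
}

# Multi-head scaled-dot-product attention. Returns the attended sequence
# (same length as `q_in`); `want_attn` additionally records the per-head
# attention weight matrices (rows sum to 1) on the returned node.
ad_mha <- function(tape, P, prefix, q_in, kv_in, n_heads, want_attn = FALSE) {
  d <- ncol(q_in$val)
  stopifnot(d %% n_heads == 0L)
  dk <- d %/% n_heads
  q <- ad_linear(tape, P, paste0(prefix, ".q"), q_in)
  k <- ad_linear(tape, P, paste0(prefix, ".k"), kv_in)
  v <- ad_linear(tape, P, paste0(prefix, ".v"), kv_in)
  heads <- vector("list", n_heads)
  attn <- if (want_attn) vector("list", n_heads) else NULL
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- ad_cols(tape, q, idx)
    kh <- ad_cols(tape, k, idx)
    vh <- ad_cols(tape, v, idx)
    sc <- ad_scale(tape, ad_matmul(tape, qh, ad_transpose(tape, kh)), 1 / sqrt(dk))
    a <- ad_rowsoftmax(tape, sc)
    if (want_attn) attn[[h]] <- a$val
    heads[[h]] <- ad_matmul(tape, a, vh)
  }
  out <- ad_linear(tape, P, paste0(prefix, ".o"), ad_cbind(tape, heads))
  if (want_attn) attr(out, "attn") <- attn
  out
}

ad_mlp <- function(tape, P, prefix, x) {
  ad_linear(tape, P, paste0(prefix, ".fc2"),
            ad_gelu(tape, ad_linear(tape, P, paste0(prefix, ".fc1"), x)))
}

# --- Adam ---------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

# Decoupled weight decay (AdamW style) applies to weight matrices only,
# never to biases, layer-norm gains/offsets or positional embeddings.
decay_mask <- function(params) {
  nm <- names(params)
  !grepl("(\\.b$|\\.g$|^pos$|fpos|ln)", nm)
}

adam_step <- function(opt, params, grads, weight_decay = 0,
                      decay = decay_mask(params)) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (k in seq_along(params)) {
    nm <- names(params)[k]
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    upd <- opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
    if (weight_decay > 0 && decay[k]) {
      upd <- upd + opt$lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(opt = opt, params = params)
}
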