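#' Configuration for the 3D vision-transformer encoder
#'
#' Desk-scale defaults (patch 8^3, embedding width 96, depth 4, 4 heads) are
#' sized so that self-supervised pretraining and the downstream survival
#' models run on a single CPU; larger settings are configuration-only.
#'
#' @param patch_size integer triple, voxel extent of one cubic patch token.
#' @param embed_dim token embedding width; must be divisible by `n_heads`.
#' @param depth number of transformer blocks.
#' @param n_heads attention heads per block.
#' @param mlp_ratio hidden width of each block's feed-forward layer, as a
#'   multiple of `embed_dim`.
#' @param projection_dim output width of the contrastive projection head.
#' @param temperature softmax temperature of the NT-Xent contrastive loss.
#' @param loss_mode how the two self-supervised objectives combine:
#'   `"product_regularized"` (reconstruction regularized multiplicatively by
#'   the contrastive term, the default), `"additive"`, `"contrastive_only"`
#'   or `"reconstruction_only"`.
#' @param lambda_con weight of the contrastive term.
#' @return a `vit_config` list.
#' @export
vit_config <- function(patch_size = c(8L, 8L, 8L), embed_dim = 96L, depth = 4L,
                       n_heads = 4L, mlp_ratio = 2, projection_dim = 32L,
                       temperature = 0.1,
                       loss_mode = c("product_regularized", "additive",
                                     "contrastive_only", "reconstruction_only"),
                       lambda_con = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(length(patch_size) == 3L, embed_dim %% n_heads == 0L,
            temperature > 0, lambda_con >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 n_heads = as.integer(n_heads), mlp_ratio = mlp_ratio,
                 projection_dim = as.integer(projection_dim),
                 temperature = temperature, loss_mode = loss_mode,
                 lambda_con = lambda_con),
            class = "vit_config")
}

#' Split a channel-stacked volume into patch tokens
#'
#' Blocks are enumerated column-major over the block grid (x-block index
#' fastest); within a token, voxels are laid out column-major over
#' (channel, x, y, z), channel fastest. `unpatchify()` inverts exactly.
#'
#' @param x a `volume_stack` or a plain 4D array (channels, X, Y, Z).
#' @param patch_size integer triple; must divide the spatial extents.
#' @return matrix with one row per patch token.
#' @export
patchify <- function(x, patch_size) {
  arr <- if (inherits(x, "volume_stack")) x$data else x
  stopifnot(length(dim(arr)) == 4L)
  d <- dim(arr)
  p <- as.integer(patch_size)
  if (any(d[2:4] %% p != 0L)) {
    stop("volume shape (", paste(d[2:4], collapse = "x"),
         ") not divisible by patch size (", paste(p, collapse = "x"), ")")
  }
  nb <- d[2:4] %/% p
  n_tok <- prod(nb)
  tok_dim <- d[1L] * prod(p)
  out <- matrix(0, n_tok, tok_dim)
  tok <- 1L
  for (bz in seq_len(nb[3L])) for (by in seq_len(nb[2L])) for (bx in seq_len(nb[1L])) {
    out[tok, ] <- as.vector(arr[, ((bx - 1L) * p[1L] + 1L):(bx * p[1L]),
                                ((by - 1L) * p[2L] + 1L):(by * p[2L]),
                                ((bz - 1L) * p[3L] + 1L):(bz * p[3L])])
    tok <- tok + 1L
  }
  attr(out, "vol_dim") <- d
  attr(out, "patch_size") <- p
  out
}

# Note: tokens are enumerated with the x-block index fastest, so token 1 is
# the corner block at (1,1,1).

#' @rdname patchify
#' @param tokens matrix produced by `patchify()` (or of the same layout).
#' @param vol_dim 4-element dimension (channels, X, Y, Z); defaults to the
#'   attribute recorded by `patchify()`.
#' @export
unpatchify <- function(tokens, patch_size = attr(tokens, "patch_size"),
                       vol_dim = attr(tokens, "vol_dim")) {
  p <- as.integer(patch_size)
  d <- as.integer(vol_dim)
  nb <- d[2:4] %/% p
  arr <- array(0, dim = d)
  tok <- 1L
  for (bz in seq_len(nb[3L])) for (by in seq_len(nb[2L])) for (bx in seq_len(nb[1L])) {
    arr[, ((bx - 1L) * p[1L] + 1L):(bx * p[1L]),
        ((by - 1L) * p[2L] + 1L):(by * p[2L]),
        ((bz - 1L) * p[3L] + 1L):(bz * p[3L])] <-
      array(tokens[tok, ], dim = c(d[1L], p))
    tok <- tok + 1L
  }
  arr
}

vit_param_init <- function(cfg, n_tokens, token_dim) {
  d <- cfg$embed_dim
  params <- c(lin_params("embed", token_dim, d),
              stats::setNames(list(matrix(stats::rnorm(n_tokens * d, sd = 0.02),
                                          n_tokens, d)), "pos"))
  for (i in seq_len(cfg$depth)) {
    pre <- paste0("blk", i)
    params <- c(params,
                ln_params(paste0(pre, ".ln1"), d),
                attn_params(paste0(pre, ".attn"), d),
                ln_params(paste0(pre, ".ln2"), d),
                mlp_params(paste0(pre, ".mlp"), d, round(d * cfg$mlp_ratio)))
  }
  c(params,
    ln_params("final", d),
    lin_params("recon", d, token_dim),
    lin_params("proj.fc1", d, d),
    lin_params("proj.fc2", d, cfg$projection_dim))
}

#' Create a (untrained) 3D ViT encoder for a fixed volume geometry
#'
#' @param cfg a [vit_config()].
#' @param volume_shape integer triple of voxel extents.
#' @param n_channels number of stacked MR contrasts (4 in standard use).
#' @param seed integer seed for parameter initialization.
#' @return a `vit_encoder` object (config, parameters, training log).
#' @export
new_encoder <- function(cfg, volume_shape, n_channels = 4L, seed = 1L) {
  stopifnot(inherits(cfg, "vit_config"))
  volume_shape <- as.integer(volume_shape)
  if (any(volume_shape %% cfg$patch_size != 0L)) {
    stop("volume_shape must be divisible by the patch size")
  }
  n_tokens <- prod(volume_shape %/% cfg$patch_size)
  token_dim <- as.integer(n_channels) * prod(cfg$patch_size)
  set.seed(seed)
  structure(list(cfg = cfg, volume_shape = volume_shape,
                 n_channels = as.integer(n_channels),
                 n_tokens = n_tokens, token_dim = token_dim,
                 params = vit_param_init(cfg, n_tokens, token_dim),
                 trained = FALSE, log = list()),
            class = "vit_encoder")
}

# Transformer trunk: patch embedding + learned positions, pre-norm blocks,
# final layer norm. Returns the token representation node (n_tokens x d).
vit_forward <- function(tape, P, cfg, tok_node) {
  x <- ad_add(tape, ad_linear(tape, P, "embed", tok_node), P("pos"))
  for (i in seq_len(cfg$depth)) {
    pre <- paste0("blk", i)
    h <- ad_ln(tape, P, paste0(pre, ".ln1"), x)
    x <- ad_add(tape, x, ad_mha(tape, P, paste0(pre, ".attn"), h, h, cfg$n_heads))
    h2 <- ad_ln(tape, P, paste0(pre, ".ln2"), x)
    x <- ad_add(tape, x, ad_mlp(tape, P, paste0(pre, ".mlp"), h2))
  }
  ad_ln(tape, P, "final", x)
}

#' Encode a volume with a (frozen) ViT encoder
#'
#' The downstream survival model always consumes frozen encodings: parameters
#' are bound as constants, so no gradient can ever reach them.
#'
#' @param encoder a `vit_encoder`.
#' @param x a `volume_stack`, a 4D array, or a pre-patchified token matrix.
#' @param allow_random_init set `TRUE` to knowingly encode with an untrained
#'   (randomly initialized) encoder, e.g. for the end-to-end baseline.
#' @return matrix of token representations (n_tokens x embed_dim).
#' @export
encode_volume <- function(encoder, x, allow_random_init = FALSE) {
  stopifnot(inherits(encoder, "vit_encoder"))
  if (!encoder$trained && !allow_random_init) {
    stop("encoder is untrained; pass allow_random_init = TRUE to opt in to a ",
         "randomly initialized encoding")
  }
  tokens <- if (is.matrix(x)) x else patchify(x, encoder$cfg$patch_size)
  stopifnot(ncol(tokens) == encoder$token_dim, nrow(tokens) == encoder$n_tokens)
  tape <- new_tape()
  P <- param_binder(tape, encoder$params, trainable = FALSE)
  vit_forward(tape, P, encoder$cfg, ad_const(tape, tokens))$val
}

# Checksum over all encoder parameters; used to assert the frozen contract.
#' @rdname encode_volume
#' @export
encoder_checksum <- function(encoder) {
  sum(vapply(encoder$params, function(p) sum(p) + sum(p^2), 0))
}
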