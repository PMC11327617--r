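# Tokenization, the two augmentations, and the two proxy-task losses.

test_that("patchify/unpatchify are exact inverses with the declared layout", {
  v <- generate_volume(0.05, shape = c(32, 32, 32), seed = 1)
  tok <- patchify(v, c(8, 8, 8))
  expect_equal(dim(tok), c(64, 4 * 512))
  expect_equal(unpatchify(tok), v$data)
  # token 1 is the corner block (x, y, z all in 1..8), channel-fastest
  corner <- as.vector(v$data[, 1:8, 1:8, 1:8])
  expect_equal(tok[1, ], corner)
  # indivisible shape errors
  expect_error(patchify(array(0, c(1, 30, 32, 32)), c(8, 8, 8)), "divisible")
})

test_that("augmentation identity, block arithmetic and swap involution hold", {
  arr <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  set.seed(1)
  same <- augment_view(arr, n_swaps = 0, cutout = list(count = 0, max_extent = c(4, 4, 4)))
  expect_identical(same$data, arr)

  ones <- array(1, c(4, 16, 16, 16))
  set.seed(2)
  cut1 <- augment_view(ones, n_swaps = 0,
                       cutout = list(count = 1, max_extent = c(4, 4, 4)))
  ext <- cut1$log$cutouts[[1]]$hi - cut1$log$cutouts[[1]]$lo + 1
  for (ch in 1:4) {
    expect_equal(sum(cut1$data[ch, , , ] == 0), prod(ext))
  }

  set.seed(3)
  sw <- augment_view(arr, n_swaps = 2, cutout = list(count = 0, max_extent = c(4, 4, 4)),
                     block_size = c(8, 8, 8))
  expect_false(identical(sw$data, arr))
  restored <- apply_block_swaps(sw$data, sw$log$swaps, c(8, 8, 8))
  expect_identical(restored, arr)

  # infeasible disjoint sampling errors: 16^3 grid with 8^3 blocks has 8 blocks
  expect_error(augment_view(arr, n_swaps = 5, block_size = c(8, 8, 8)),
               "disjoint")
})

test_that("reconstruction loss is the mean absolute voxel error", {
  v <- generate_volume(0.03, shape = c(16, 16, 16), seed = 4)
  expect_equal(reconstruction_loss(v, v), 0)
  shifted <- v
  shifted$data <- v$data + 1
  expect_equal(reconstruction_loss(shifted, v), 1)
  set.seed(5)
  other <- v
  other$data <- v$data + rnorm(length(v$data))
  expect_equal(reconstruction_loss(other, v),
               sum(abs(other$data - v$data)) / length(v$data))
  expect_error(reconstruction_loss(array(0, c(1, 2, 2, 2)), v), "shape")
})

test_that("contrastive loss has the collapse value, separation limit and rotation invariance", {
  for (N in c(2, 5)) for (tau in c(0.05, 0.5)) {
    z <- matrix(rep(c(1, 2, 3), each = 2 * N), 2 * N, 3)
    expect_equal(contrastive_loss(z, tau), log(2 * N - 1), tolerance = 1e-9)
  }
  # orthogonal positives, tau -> 0: loss -> 0
  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  z <- rbind(a, b, a, b)
  expect_lt(contrastive_loss(z, tau = 0.01), 1e-6)
  # invariance under a common rotation
  set.seed(6)
  z2 <- matrix(rnorm(8 * 4), 8, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(contrastive_loss(z2, 0.1), contrastive_loss(z2 %*% Q, 0.1),
               tolerance = 1e-9)
  expect_error(contrastive_loss(rbind(z2, 0, 0), 0.1), "zero-norm")
})

test_that("loss modes combine as documented", {
  expect_equal(combined_ssl_loss(0.7, 9, "reconstruction_only"), 0.7)
  expect_equal(combined_ssl_loss(9, 0.4, "contrastive_only"), 0.4)
  expect_equal(combined_ssl_loss(0.2, 0.3, "additive", 1), 0.5)
  expect_equal(combined_ssl_loss(0.2, 0.3, "product_regularized", 1), 0.26)
  expect_error(combined_ssl_loss(1, 1, "bogus"), "unknown")
})

test_that("encoder contracts: opt-in for random init, determinism, token count", {
  cfg <- vit_config(patch_size = c(8, 8, 8), embed_dim = 32, depth = 2,
                    n_heads = 2)
  enc <- new_encoder(cfg, c(16, 16, 16), seed = 1)
  v <- generate_volume(0.05, shape = c(16, 16, 16), seed = 2)
  expect_error(encode_volume(enc, v), "untrained")
  e1 <- encode_volume(enc, v, allow_random_init = TRUE)
  e2 <- encode_volume(enc, v, allow_random_init = TRUE)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(8, 32))  # (16/8)^3 tokens x embed_dim
  expect_error(new_encoder(cfg, c(15, 16, 16)), "divisible")
})

test_that("a short pretraining run reduces the reconstruction loss and matches the numeric losses", {
  cfg <- vit_config(patch_size = c(8, 8, 8), embed_dim = 32, depth = 2,
                    n_heads = 2, projection_dim = 16)
  enc <- new_encoder(cfg, c(16, 16, 16), seed = 3)
  set.seed(4)
  vols <- lapply(1:8, function(i) generate_volume(runif(1, 0.02, 0.12),
                                                  shape = c(16, 16, 16), seed = i))
  enc <- pretrain_encoder(enc, vols, epochs = 6, batch_size = 8,
                          n_swaps = 2, cutout = list(count = 1, max_extent = c(4, 4, 4)),
                          seed = 5)
  expect_true(enc$trained)
  expect_lt(enc$log$rec[6], enc$log$rec[1])
  # the tape-side contrastive value agrees with the exported numeric loss
  ad <- asNamespace("gliosurv")
  set.seed(8)
  toks <- lapply(vols[1:4], patchify, patch_size = cfg$patch_size)
  views <- list(toks, lapply(vols[1:4], function(v) {
    patchify(augment_view(v, 1, list(count = 1, max_extent = c(4, 4, 4)),
                          block_size = cfg$patch_size)$data, cfg$patch_size)
  }))
  tape <- ad$new_tape()
  P <- ad$param_binder(tape, enc$params)
  g <- ad$ssl_batch_graph(tape, P, cfg, toks, views)
  # recompute the contrastive term outside the tape
  emb <- t(sapply(unlist(views, recursive = FALSE), function(tk) {
    reps <- encode_volume(enc, tk)
    pooled <- colMeans(reps)
    h <- pooled %*% enc$params[["proj.fc1.W"]] + enc$params[["proj.fc1.b"]]
    gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
    gelu(h) %*% enc$params[["proj.fc2.W"]] + enc$params[["proj.fc2.b"]]
  }))
  expect_equal(g$con, contrastive_loss(emb, cfg$temperature), tolerance = 1e-8)
})
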