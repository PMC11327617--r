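# Attention fusion operations: hand-checked values, shape/equivariance
# contracts, and agreement between the exported matrix forms and the
# autodiff graph used in training.

rand_params <- function(d, nh = 1L, with_o = FALSE, seed = 1) {
  set.seed(seed)
  p <- list(Wq = matrix(rnorm(d * d), d, d), Wk = matrix(rnorm(d * d), d, d),
            Wv = matrix(rnorm(d * d), d, d), n_heads = nh)
  if (with_o) p$Wo <- matrix(rnorm(d * d), d, d)
  p
}

test_that("cross-attention reproduces a step-by-step hand evaluation", {
  alpha <- matrix(c(1, 0, 0.5, -1), 2, 2)
  beta <- matrix(c(0.2, 1, -0.4, 0.7), 2, 2)
  p <- list(Wq = matrix(c(1, 0.5, -0.3, 1), 2, 2),
            Wk = matrix(c(0.8, 0, 0.2, -1), 2, 2),
            Wv = matrix(c(1, 1, 0, 0.5), 2, 2), n_heads = 1L)
  got <- cross_attention(alpha, beta, p)
  # independent evaluation
  Q <- alpha %*% p$Wq; K <- beta %*% p$Wk; V <- beta %*% p$Wv
  S <- Q %*% t(K) / sqrt(2)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_equal(unclass(got), A %*% V, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowSums(attr(got, "attn")[[1]]), c(1, 1), tolerance = 1e-9)
})

test_that("softmax-over-one-key and uniform-attention degeneracies hold", {
  d <- 4
  p <- rand_params(d, seed = 2)
  alpha <- matrix(rnorm(3 * d), 3, d)
  beta1 <- matrix(rnorm(d), 1, d)
  out <- cross_attention(alpha, beta1, p)
  expect_equal(out[1, ], drop(beta1 %*% p$Wv), ignore_attr = TRUE)
  expect_equal(out[2, ], out[1, ])
  # identical keys: every output row is the mean of the value rows
  betaI <- matrix(rep(rnorm(d), each = 5), 5, d)
  outI <- cross_attention(alpha, betaI, p)
  expect_equal(outI[1, ], colMeans(betaI %*% p$Wv), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("bidirectional fusion has the right lengths, equivariance and isolation", {
  d <- 4
  params <- list(img = rand_params(d, seed = 3), clin = rand_params(d, seed = 4))
  img <- matrix(rnorm(6 * d), 6, d)
  clin <- matrix(rnorm(3 * d), 3, d)
  fu <- bidirectional_fusion(img, clin, params)
  expect_equal(nrow(fu$img_hat), 6)
  expect_equal(nrow(fu$clin_hat), 3)
  # permuting image tokens permutes img_hat rows identically
  perm <- c(4, 1, 6, 2, 5, 3)
  fu2 <- bidirectional_fusion(img[perm, ], clin, params)
  expect_equal(fu2$img_hat, fu$img_hat[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # directions use disjoint parameters
  pz <- params
  pz$img <- lapply(params$img, function(w) if (is.matrix(w)) w * 0 else w)
  fu3 <- bidirectional_fusion(img, clin, pz)
  expect_equal(fu3$clin_hat, fu$clin_hat)
  expect_false(isTRUE(all.equal(fu3$img_hat, fu$img_hat)))
})

test_that("final attention concatenates keys and is invariant to their order", {
  d <- 4
  p <- rand_params(d, nh = 2L, with_o = TRUE, seed = 5)
  img_hat <- matrix(rnorm(5 * d), 5, d)
  clin_hat <- matrix(rnorm(2 * d), 2, d)
  q <- matrix(rnorm(2 * d), 2, d)
  a <- final_attention(img_hat, clin_hat, q, p)
  expect_equal(nrow(a), 2)
  expect_equal(nrow(attr(a, "attn")[[1]]) * 0 + ncol(attr(a, "attn")[[1]]), 7)
  # attention over keys is permutation invariant: swapped concat order
  b <- cross_attention(q, rbind(clin_hat, img_hat), p)
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("attention pooling is a convex combination of value rows", {
  d <- 4
  set.seed(6)
  p <- list(q = rnorm(d), Wk = matrix(rnorm(d * d), d, d),
            Wv = matrix(rnorm(d * d), d, d))
  one <- matrix(rnorm(d), 1, d)
  expect_equal(drop(attention_pool(one, p)), drop(one %*% p$Wv),
               ignore_attr = TRUE)
  same <- matrix(rep(rnorm(d), each = 4), 4, d)
  expect_equal(drop(attention_pool(same, p)), drop(same[1, , drop = FALSE] %*% p$Wv),
               tolerance = 1e-9, ignore_attr = TRUE)
  # hull membership, coordinatewise
  sq <- matrix(rnorm(6 * d), 6, d)
  V <- sq %*% p$Wv
  out <- drop(attention_pool(sq, p))
  expect_true(all(out >= apply(V, 2, min) - 1e-9))
  expect_true(all(out <= apply(V, 2, max) + 1e-9))
  expect_error(attention_pool(matrix(nrow = 0, ncol = d), p), "empty")
})

test_that("clinical encoder and logit head satisfy their contracts", {
  set.seed(7)
  pe <- list(W1 = matrix(rnorm(5 * 8), 5, 8), b1 = rnorm(8),
             W2 = matrix(rnorm(8 * 12), 8, 12), b2 = rnorm(12))
  x <- rnorm(5)
  expect_identical(clinical_encoder(x, pe, L_c = 4), clinical_encoder(x, pe, L_c = 4))
  expect_equal(dim(clinical_encoder(x, pe, L_c = 4)), c(4L, 3L))
  pz <- list(W1 = pe$W1 * 0, b1 = pe$b1 * 0, W2 = pe$W2 * 0, b2 = pe$b2 * 0)
  expect_true(all(clinical_encoder(x, pz, L_c = 4) == 0))
  expect_error(clinical_encoder(c(NaN, 1, 1, 1, 1), pe), "finite")

  ph <- list(W1 = matrix(rnorm(16), 4, 4), b1 = rnorm(4),
             W2 = matrix(rnorm(4 * 6), 4, 6), b2 = rnorm(6))
  lg <- predict_logits(rnorm(4), ph)
  expect_equal(ncol(lg), 6)  # K = 1, 5 bins + beyond cell
  expect_true(all(is.finite(predict_logits(c(1e3, -1e3, 1e3, -1e3), ph))))
})

test_that("self-attention variant equals cross-attention with itself", {
  d <- 4
  p <- rand_params(d, nh = 2L, with_o = TRUE, seed = 8)
  x <- matrix(rnorm(3 * d), 3, d)
  expect_identical(unclass(self_attention_variant(x, p)),
                   unclass(cross_attention(x, x, p)))
  one <- matrix(rnorm(d), 1, d)
  po <- rand_params(d, seed = 9)
  expect_equal(drop(self_attention_variant(one, po)), drop(one %*% po$Wv),
               ignore_attr = TRUE)
})

test_that("the exported attention matches the training-tape attention", {
  ad <- asNamespace("gliosurv")
  set.seed(10)
  d <- 8
  params <- ad$attn_params("at", d)
  q_in <- matrix(rnorm(3 * d), 3, d)
  kv_in <- matrix(rnorm(5 * d), 5, d)
  tape <- ad$new_tape()
  P <- ad$param_binder(tape, params, trainable = FALSE)
  node <- ad$ad_mha(tape, P, "at", ad$ad_const(tape, q_in),
                    ad$ad_const(tape, kv_in), n_heads = 2)
  p2 <- list(Wq = params[["at.q.W"]], bq = params[["at.q.b"]],
             Wk = params[["at.k.W"]], bk = params[["at.k.b"]],
             Wv = params[["at.v.W"]], bv = params[["at.v.b"]],
             Wo = params[["at.o.W"]], bo = params[["at.o.b"]], n_heads = 2L)
  expect_equal(node$val, unclass(cross_attention(q_in, kv_in, p2)),
               ignore_attr = TRUE, tolerance = 1e-12)
})
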