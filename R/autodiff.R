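# Reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a base-R numeric matrix; nodes are environments
# holding the forward value, an accumulated gradient, and a backward closure.
# Values are computed eagerly at op creation, so a "tape" is simply the
# creation-ordered node list; the backward pass walks it in reverse.
# This is deliberately small: only the ops the survival models need exist.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

.ad_push <- function(tape, val, track, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$track <- track
  nd$bw <- bw
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# Constants never receive gradients; parameters do.
ad_const <- function(tape, x) .ad_push(tape, .as_mat(x), FALSE)
ad_param <- function(tape, x) .ad_push(tape, .as_mat(x), TRUE)

.acc <- function(nd, g) {
  if (nd$track) {
    nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  }
  invisible(NULL)
}

ad_backward <- function(tape, out) {
  out$grad <- matrix(1, nrow(out$val), ncol(out$val))
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (nd$track && !is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

.tr <- function(...) {
  for (nd in list(...)) if (nd$track) return(TRUE)
  FALSE
}

ad_matmul <- function(tape, a, b) {
  v <- a$val %*% b$val
  .ad_push(tape, v, .tr(a, b), function(g) {
    .acc(a, g %*% t(b$val))
    .acc(b, t(a$val) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  .ad_push(tape, a$val + b$val, .tr(a, b), function(g) {
    .acc(a, g)
    .acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  .ad_push(tape, a$val - b$val, .tr(a, b), function(g) {
    .acc(a, g)
    .acc(b, -g)
  })
}

# Elementwise product; either operand may be a 1x1 scalar node.
ad_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  if (length(av) == 1L && length(bv) > 1L) return(ad_mul(tape, b, a))
  if (length(bv) == 1L) {
    v <- av * bv[1L]
    return(.ad_push(tape, v, .tr(a, b), function(g) {
      .acc(a, g * bv[1L])
      .acc(b, matrix(sum(g * av), 1L, 1L))
    }))
  }
  .ad_push(tape, av * bv, .tr(a, b), function(g) {
    .acc(a, g * bv)
    .acc(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  .ad_push(tape, a$val * s, a$track, function(g) .acc(a, g * s))
}

ad_addc <- function(tape, a, cst) {
  .ad_push(tape, a$val + cst, a$track, function(g) .acc(a, g))
}

# Add a 1 x k row vector to every row of an n x k matrix (bias add).
ad_add_rowvec <- function(tape, a, v) {
  vv <- v$val
  val <- sweep(a$val, 2L, vv[1L, ], "+")
  .ad_push(tape, val, .tr(a, v), function(g) {
    .acc(a, g)
    .acc(v, matrix(colSums(g), 1L))
  })
}

# v (n x 1) recycled across columns, minus a (n x m).
ad_colvec_minus <- function(tape, v, a) {
  n <- nrow(a$val); m <- ncol(a$val)
  val <- matrix(v$val[, 1L], n, m) - a$val
  .ad_push(tape, val, .tr(v, a), function(g) {
    .acc(v, matrix(rowSums(g), n, 1L))
    .acc(a, -g)
  })
}

ad_transpose <- function(tape, a) {
  .ad_push(tape, t(a$val), a$track, function(g) .acc(a, t(g)))
}

ad_cols <- function(tape, a, idx) {
  d <- dim(a$val)
  .ad_push(tape, a$val[, idx, drop = FALSE], a$track, function(g) {
    g0 <- matrix(0, d[1L], d[2L])
    g0[, idx] <- g
    .acc(a, g0)
  })
}

ad_rows <- function(tape, a, idx) {
  d <- dim(a$val)
  .ad_push(tape, a$val[idx, , drop = FALSE], a$track, function(g) {
    g0 <- matrix(0, d[1L], d[2L])
    g0[idx, ] <- g
    .acc(a, g0)
  })
}

ad_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(nd) nd$val)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  .ad_push(tape, do.call(rbind, vals), any(vapply(nodes, function(nd) nd$track, TRUE)),
    function(g) {
      for (i in seq_along(nodes)) {
        .acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
      }
    })
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(nd) nd$val)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  .ad_push(tape, do.call(cbind, vals), any(vapply(nodes, function(nd) nd$track, TRUE)),
    function(g) {
      for (i in seq_along(nodes)) {
        .acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
      }
    })
}

ad_rowsoftmax <- function(tape, a) {
  av <- a$val
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  p <- e / rowSums(e)
  .ad_push(tape, p, a$track, function(g) {
    .acc(a, p * (g - rowSums(g * p)))
  })
}

ad_rowlogsumexp <- function(tape, a) {
  av <- a$val
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  se <- rowSums(e)
  val <- matrix(mx + log(se), ncol = 1L)
  p <- e / se
  .ad_push(tape, val, a$track, function(g) {
    .acc(a, p * matrix(g[, 1L], nrow(av), ncol(av)))
  })
}

# Per-row layer normalization with learnable gain/offset (1 x d each).
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  av <- a$val
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  sdv <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sdv
  val <- sweep(xhat * matrix(gamma$val[1L, ], nrow(av), d, byrow = TRUE), 2L,
               beta$val[1L, ], "+")
  .ad_push(tape, val, .tr(a, gamma, beta), function(g) {
    gmat <- matrix(gamma$val[1L, ], nrow(av), d, byrow = TRUE)
    dxhat <- g * gmat
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sdv
    .acc(a, dx)
    .acc(gamma, matrix(colSums(g * xhat), 1L))
    .acc(beta, matrix(colSums(g), 1L))
  })
}

ad_relu <- function(tape, a) {
  av <- a$val
  .ad_push(tape, pmax(av, 0), a$track, function(g) .acc(a, g * (av > 0)))
}

ad_gelu <- function(tape, a) {
  # tanh approximation of the Gaussian error linear unit
  x <- a$val
  c0 <- sqrt(2 / pi)
  u <- c0 * (x + 0.044715 * x^3)
  th <- tanh(u)
  val <- 0.5 * x * (1 + th)
  .ad_push(tape, val, a$track, function(g) {
    dd <- 0.5 * (1 + th) + 0.5 * x * (1 - th^2) * c0 * (1 + 3 * 0.044715 * x^2)
    .acc(a, g * dd)
  })
}

ad_tanh <- function(tape, a) {
  th <- tanh(a$val)
  .ad_push(tape, th, a$track, function(g) .acc(a, g * (1 - th^2)))
}

ad_exp <- function(tape, a) {
  e <- exp(a$val)
  .ad_push(tape, e, a$track, function(g) .acc(a, g * e))
}

# log with a floor: values below eps are clamped and get zero gradient.
ad_log_clamped <- function(tape, a, eps = 1e-12) {
  av <- a$val
  cl <- pmax(av, eps)
  .ad_push(tape, log(cl), a$track, function(g) .acc(a, g * (av > eps) / cl))
}

ad_abs <- function(tape, a) {
  av <- a$val
  .ad_push(tape, abs(av), a$track, function(g) .acc(a, g * sign(av)))
}

ad_mean_all <- function(tape, a) {
  n <- length(a$val)
  .ad_push(tape, matrix(mean(a$val), 1L, 1L), a$track, function(g) {
    .acc(a, matrix(g[1L] / n, nrow(a$val), ncol(a$val)))
  })
}

ad_sum_all <- function(tape, a) {
  .ad_push(tape, matrix(sum(a$val), 1L, 1L), a$track, function(g) {
    .acc(a, matrix(g[1L], nrow(a$val), ncol(a$val)))
  })
}

ad_rowsums <- function(tape, a) {
  d <- dim(a$val)
  .ad_push(tape, matrix(rowSums(a$val), ncol = 1L), a$track, function(g) {
    .acc(a, matrix(g[, 1L], d[1L], d[2L]))
  })
}

# Rows rescaled to unit Euclidean norm; errors on (near-)zero rows because a
# zero embedding has no direction for the cosine similarity to use.
ad_l2normalize_rows <- function(tape, a) {
  av <- a$val
  nrm <- sqrt(rowSums(av^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero-norm embedding row")
  xhat <- av / nrm
  .ad_push(tape, xhat, a$track, function(g) {
    .acc(a, (g - xhat * rowSums(g * xhat)) / nrm)
  })
}
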