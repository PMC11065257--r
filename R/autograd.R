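# Minimal reverse-mode automatic differentiation over plain R arrays.
#
# A tape records nodes in creation order (a valid topological order, since the
# graph is built during the forward pass). Each node is an environment holding
# its value, an optional backward closure mapping the upstream gradient to the
# gradients of its parents, and the accumulated gradient. Only the handful of
# operations the segmentation networks need are implemented; every operation
# with a non-trivial adjoint is covered by finite-difference checks in the
# test suite.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ag_tape"
  e
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
    nd$id <- n
  } else {
    nd$id <- NA_integer_
  }
  class(nd) <- "ag_nd"
  nd
}

is_ag_node <- function(x) inherits(x, "ag_nd")

ag_value <- function(x) if (is_ag_node(x)) x$value else x

# Leaf parameter (receives gradient, has no backward of its own).
ag_leaf <- function(tape, value) ag_node(tape, value)

# Wrap a whole parameter list (named arrays) as leaves.
ag_leaves <- function(tape, params) lapply(params, function(p) ag_leaf(tape, p))

# Reverse sweep from a scalar node. Gradients accumulate in each node's $grad.
ag_backward <- function(tape, node) {
  stopifnot(is_ag_node(node), length(node$value) == 1L)
  node$grad <- 1
  for (i in seq.int(node$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (!is_ag_node(p)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(node)
}

ag_grad <- function(node) node$grad

## ---- elementwise ----------------------------------------------------------

ag_add <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(tape, av + bv, list(a, b), function(g) {
    list(if (is_ag_node(a)) g else NULL, if (is_ag_node(b)) g else NULL)
  })
}

ag_sub <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(tape, av - bv, list(a, b), function(g) {
    list(if (is_ag_node(a)) g else NULL, if (is_ag_node(b)) -g else NULL)
  })
}

ag_mul <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(tape, av * bv, list(a, b), function(g) {
    list(if (is_ag_node(a)) g * bv else NULL, if (is_ag_node(b)) g * av else NULL)
  })
}

ag_relu <- function(tape, x) {
  v <- ag_value(x)
  keep <- v > 0
  ag_node(tape, v * keep, list(x), function(g) list(g * keep))
}

ag_sigmoid <- function(tape, x) {
  s <- stats::plogis(ag_value(x))
  ag_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# Weighted sum of scalar nodes: sum_i w_i x_i (loss composition).
ag_axpy <- function(tape, xs, w = rep(1, length(xs))) {
  v <- sum(vapply(xs, ag_value, numeric(1)) * w)
  ag_node(tape, v, xs, function(g) as.list(g * w))
}

## ---- spatial ops on (H, W, C) arrays -------------------------------------

.proto_cache <- new.env(parent = emptyenv())

# im2col linear-index matrix for a padded (Hp, Wp, C) array; cached.
im2col_index <- function(H, W, C, kh, kw, pad) {
  key <- paste("ic", H, W, C, kh, kw, pad, sep = "_")
  out <- .proto_cache[[key]]
  if (!is.null(out)) return(out)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  pr <- rep(seq_len(kh), times = kw)
  pc <- rep(seq_len(kw), each = kh)
  R <- outer(rep(seq_len(Ho) - 1L, times = Wo), pr, "+")
  Cc <- outer(rep(seq_len(Wo) - 1L, each = Ho), pc, "+")
  lin <- R + (Cc - 1L) * Hp
  nk <- kh * kw
  idx <- matrix(0L, Ho * Wo, nk * C)
  for (ch in seq_len(C)) {
    idx[, (ch - 1L) * nk + seq_len(nk)] <- lin + (ch - 1L) * Hp * Wp
  }
  # stored as a plain vector: matrix indexing of an array would switch to
  # coordinate semantics whenever ncol(idx) equals the array's rank
  out <- list(idx = as.integer(idx), nrow = Ho * Wo, ncol = nk * C,
              Ho = Ho, Wo = Wo)
  .proto_cache[[key]] <- out
  out
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Plain cross-correlation used by ag_conv2d and its input gradient.
conv2d_value <- function(xv, Wv, bv = NULL, pad = 1L, want_cols = FALSE) {
  d <- dim(xv); kh <- dim(Wv)[1]; kw <- dim(Wv)[2]
  Cin <- dim(Wv)[3]; Cout <- dim(Wv)[4]
  ii <- im2col_index(d[1], d[2], Cin, kh, kw, as.integer(pad))
  xp <- pad_hw(xv, as.integer(pad))
  Xc <- xp[ii$idx]
  dim(Xc) <- c(ii$nrow, ii$ncol)
  Y <- Xc %*% matrix(Wv, kh * kw * Cin, Cout)
  if (!is.null(bv)) Y <- sweep(Y, 2L, bv, "+")
  list(out = array(Y, c(ii$Ho, ii$Wo, Cout)), Xc = if (want_cols) Xc)
}

# 2-D convolution: x (H,W,Cin), W (kh,kw,Cin,Cout), b (Cout). Stride is
# always 1 here (downsampling is by pooling), so the input gradient is
# itself a convolution of the output gradient with the 180-degree-rotated,
# channel-transposed kernel; the whole backward pass stays in BLAS.
ag_conv2d <- function(tape, x, W, b, stride = 1L, pad = 1L) {
  stopifnot(stride == 1L)
  xv <- ag_value(x); Wv <- ag_value(W); bv <- ag_value(b)
  d <- dim(xv); kh <- dim(Wv)[1]; kw <- dim(Wv)[2]
  Cin <- dim(Wv)[3]; Cout <- dim(Wv)[4]
  stopifnot(d[3] == Cin)
  fw <- conv2d_value(xv, Wv, bv, pad, want_cols = TRUE)
  ag_node(tape, fw$out, list(x, W, b), function(g) {
    do <- dim(fw$out)
    gm <- matrix(g, do[1] * do[2], Cout)
    gW <- if (is_ag_node(W)) array(crossprod(fw$Xc, gm), dim(Wv)) else NULL
    gb <- if (is_ag_node(b)) colSums(gm) else NULL
    gx <- NULL
    if (is_ag_node(x)) {
      Wrot <- aperm(Wv[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
      gx <- conv2d_value(g, Wrot, NULL, kh - 1L - as.integer(pad))$out
    }
    list(gx, gW, gb)
  })
}

# 2x2 (factor f) average pooling.
ag_avgpool <- function(tape, x, f = 2L) {
  v <- ag_value(x); d <- dim(v)
  Hf <- d[1] %/% f; Wf <- d[2] %/% f
  y <- v
  dim(y) <- c(f, Hf * f * Wf * d[3])
  y <- colMeans(y)
  dim(y) <- c(Hf, f, Wf * d[3])
  y <- aperm(y, c(2, 1, 3))
  dim(y) <- c(f, Hf * Wf * d[3])
  y <- colMeans(y)
  dim(y) <- c(Hf, Wf, d[3])
  ag_node(tape, y, list(x), function(g) {
    ri <- rep(seq_len(Hf), each = f); ci <- rep(seq_len(Wf), each = f)
    list(g[ri, ci, , drop = FALSE] / (f * f))
  })
}

ag_upsample <- function(tape, x, f = 2L) {
  v <- ag_value(x); d <- dim(v)
  ri <- rep(seq_len(d[1]), each = f); ci <- rep(seq_len(d[2]), each = f)
  y <- v[ri, ci, , drop = FALSE]
  ag_node(tape, y, list(x), function(g) {
    z <- g
    dim(z) <- c(f, d[1] * f * d[2] * d[3])
    z <- colSums(z)
    dim(z) <- c(d[1], f, d[2] * d[3])
    z <- aperm(z, c(2, 1, 3))
    dim(z) <- c(f, d[1] * d[2] * d[3])
    z <- colSums(z)
    dim(z) <- d
    list(z)
  })
}

# Nearest-neighbour downsample by integer factor (top-left sample per block);
# preserves binary values.
ag_subsample <- function(tape, x, f = 2L) {
  v <- ag_value(x); d <- dim(v)
  ri <- seq.int(1L, d[1], by = f); ci <- seq.int(1L, d[2], by = f)
  y <- v[ri, ci, , drop = FALSE]
  ag_node(tape, y, list(x), function(g) {
    z <- array(0, d)
    z[ri, ci, ] <- g
    list(z)
  })
}

# Concatenate along the channel axis.
ag_concat_c <- function(tape, xs) {
  vs <- lapply(xs, ag_value)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  out <- array(unlist(vs, use.names = FALSE), c(d1[1], d1[2], sum(cs)))
  ends <- cumsum(cs); starts <- ends - cs + 1
  ag_node(tape, out, xs, function(g) {
    lapply(seq_along(xs), function(j) {
      if (!is_ag_node(xs[[j]])) return(NULL)
      g[, , starts[j]:ends[j], drop = FALSE]
    })
  })
}

# Global average pooling: (H,W,C) -> C-vector.
ag_gap <- function(tape, x) {
  v <- ag_value(x); d <- dim(v)
  y <- colMeans(matrix(v, d[1] * d[2], d[3]))
  ag_node(tape, y, list(x), function(g) {
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d))
  })
}

# Fully connected: vector (Cin) x W (Cin,Cout) + b.
ag_dense <- function(tape, x, W, b) {
  xv <- ag_value(x); Wv <- ag_value(W); bv <- ag_value(b)
  y <- drop(matrix(xv, 1) %*% Wv) + bv
  ag_node(tape, y, list(x, W, b), function(g) {
    list(if (is_ag_node(x)) drop(Wv %*% g) else NULL,
         if (is_ag_node(W)) outer(xv, g) else NULL,
         if (is_ag_node(b)) g else NULL)
  })
}

# Coerce a 2-D image (node or plain matrix) to an (H,W,1) array; plain
# inputs stay plain constants so no input gradient is computed for them.
ag_as_image3d <- function(tape, image) {
  v <- ag_value(image)
  if (!is.matrix(v)) return(image)
  a <- array(v, c(nrow(v), ncol(v), 1L))
  if (is_ag_node(image)) {
    ag_node(tape, a, list(image), function(g) {
      list(matrix(g, dim(g)[1], dim(g)[2]))
    })
  } else {
    a
  }
}

ag_reshape <- function(tape, x, dims) {
  v <- ag_value(x)
  d0 <- if (is.null(dim(v))) length(v) else dim(v)
  y <- v
  dim(y) <- dims
  ag_node(tape, y, list(x), function(g) {
    dim(g) <- d0
    list(g)
  })
}

# Stack two prototype matrices (K1,C) and (K2,C) by rows.
ag_rbind2 <- function(tape, a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  k1 <- nrow(av)
  ag_node(tape, rbind(av, bv), list(a, b), function(g) {
    list(if (is_ag_node(a)) g[seq_len(k1), , drop = FALSE] else NULL,
         if (is_ag_node(b)) g[-seq_len(k1), , drop = FALSE] else NULL)
  })
}

# Extract channel k of an (H,W,C) array as a matrix.
ag_channel <- function(tape, x, k) {
  v <- ag_value(x); d <- dim(v)
  ag_node(tape, v[, , k], list(x), function(g) {
    z <- array(0, d)
    z[, , k] <- g
    list(z)
  })
}

## ---- prototype-space ops --------------------------------------------------

# Linear pooling: F (H,W,C) against a fixed (HW x K) weight matrix whose
# columns are averaging weights; returns (K, C) prototype matrix.
ag_pool_mat <- function(tape, x, A) {
  v <- ag_value(x); d <- dim(v)
  Fm <- matrix(v, d[1] * d[2], d[3])
  P <- crossprod(A, Fm)
  ag_node(tape, P, list(x), function(g) {
    list(array(A %*% g, d))
  })
}

# Scaled cosine similarity of every query pixel against every prototype.
# Fq (H,W,C), P (K,C) -> (H,W,K). Norms are smoothed in quadrature with eps,
# so zero vectors give similarity 0 with a finite gradient.
ag_cosine <- function(tape, Fq, P, alpha_scale = 20, eps = 1e-8) {
  fv <- ag_value(Fq); Pv <- ag_value(P)
  d <- dim(fv); K <- nrow(Pv)
  Fm <- matrix(fv, d[1] * d[2], d[3])
  nf <- sqrt(rowSums(Fm^2) + eps^2)
  np <- sqrt(rowSums(Pv^2) + eps^2)
  Dot <- Fm %*% t(Pv)
  Cm <- Dot / outer(nf, np)
  out <- array(alpha_scale * Cm, c(d[1], d[2], K))
  ag_node(tape, out, list(Fq, P), function(g) {
    dC <- alpha_scale * matrix(g, d[1] * d[2], K)
    B <- dC / outer(nf, np)
    gF <- NULL; gP <- NULL
    if (is_ag_node(Fq)) {
      gFm <- B %*% Pv - Fm * (rowSums(dC * Cm) / nf^2)
      gF <- array(gFm, d)
    }
    if (is_ag_node(P)) {
      gP <- crossprod(B, Fm) - Pv * (colSums(dC * Cm) / np^2)
    }
    list(gF, gP)
  })
}

# Prototype allocation: softmax-weighted (over prototype axis k) average of
# the similarity maps. D (H,W,K) -> (H,W).
ag_alloc <- function(tape, D) {
  v <- ag_value(D); d <- dim(v); K <- d[3]
  Dm <- matrix(v, d[1] * d[2], K)
  e <- exp(Dm - apply(Dm, 1, max))
  S <- e / rowSums(e)
  PM <- rowSums(Dm * S)
  out <- matrix(PM, d[1], d[2])
  ag_node(tape, out, list(D), function(g) {
    gv <- c(g)
    gD <- S * (1 + Dm - PM) * gv
    list(array(gD, d))
  })
}

# Guide features: at each pixel place the prototype with the largest
# similarity (ties -> lowest index). The selection itself carries no
# gradient; gradient flows into the selected prototype values only.
ag_guide <- function(tape, D, P) {
  Dv <- ag_value(D); Pv <- ag_value(P)
  d <- dim(Dv); K <- d[3]
  Dm <- matrix(Dv, d[1] * d[2], K)
  kstar <- max.col(Dm, ties.method = "first")
  FG <- array(Pv[kstar, , drop = FALSE], c(d[1], d[2], ncol(Pv)))
  ag_node(tape, FG, list(P), function(g) {
    gm <- matrix(g, d[1] * d[2], ncol(Pv))
    acc <- rowsum(gm, group = kstar)
    gP <- matrix(0, K, ncol(Pv))
    gP[as.integer(rownames(acc)), ] <- acc
    list(gP)
  })
}

## ---- losses ---------------------------------------------------------------

# Pixelwise two-class softmax over (fg, bg) score maps + cross-entropy against
# a binary label, averaged over pixels. Probabilities are clamped at 1e-7.
ag_softmax_ce <- function(tape, fg, bg, label) {
  fv <- ag_value(fg); bv <- ag_value(bg)
  z <- fv - bv
  p <- stats::plogis(z)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  y <- label
  n <- length(y)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  ag_node(tape, loss, list(fg, bg), function(g) {
    dz <- g * (p - y) / n
    list(if (is_ag_node(fg)) dz else NULL, if (is_ag_node(bg)) -dz else NULL)
  })
}

# Binary cross-entropy of sigmoid(z) against a 0/1 target, numerically stable.
ag_bce_logit <- function(tape, z, target) {
  zv <- ag_value(z)
  loss <- max(zv, 0) - target * zv + log1p(exp(-abs(zv)))
  ag_node(tape, loss, list(z), function(g) {
    list(g * (stats::plogis(zv) - target))
  })
}

# Straight-through hard threshold: forward emits the binary mask p > 0.5,
# backward passes the gradient unchanged to the soft probability.
ag_hard_st <- function(tape, p) {
  v <- (ag_value(p) > 0.5) * 1
  ag_node(tape, v, list(p), function(g) list(g))
}
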