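# Brute-force reference implementations, written independently of the
# package's vectorised code paths: explicit loops over pixels, windows and
# prototypes. Used by the unit tests and the equation-oracle acceptance
# suite.

rand_grid <- function(H, W, C) array(stats::rnorm(H * W * C), c(H, W, C))

rand_mask <- function(H, W, p = 0.4) {
  m <- matrix(stats::rbinom(H * W, 1, p), H, W)
  if (sum(m) == 0) m[sample.int(H * W, 1)] <- 1
  m
}

# windowed average pooling by exhaustive loops; returns list(vectors, occ)
oracle_window_pool <- function(F_grid, M, window_scale) {
  H <- dim(F_grid)[1]; W <- dim(F_grid)[2]; C <- dim(F_grid)[3]
  wh <- max(1, ceiling(window_scale * H))
  ww <- max(1, ceiling(window_scale * W))
  vecs <- NULL; occ <- NULL
  for (cj in seq(1, W, by = ww)) {
    for (ri in seq(1, H, by = wh)) {
      rr <- ri:min(ri + wh - 1, H)
      cc <- cj:min(cj + ww - 1, W)
      v <- numeric(C); o <- 0; n <- 0
      for (r in rr) for (cl in cc) {
        v <- v + F_grid[r, cl, ]
        o <- o + M[r, cl]
        n <- n + 1
      }
      vecs <- rbind(vecs, v / n)
      occ <- c(occ, o / n)
    }
  }
  list(vectors = vecs, occ = occ)
}

oracle_masked_pool <- function(F_grid, M) {
  C <- dim(F_grid)[3]
  num <- numeric(C); den <- 0
  for (r in seq_len(dim(F_grid)[1])) for (cl in seq_len(dim(F_grid)[2])) {
    num <- num + F_grid[r, cl, ] * M[r, cl]
    den <- den + M[r, cl]
  }
  num / den
}

oracle_cosine <- function(fq, p, alpha = 20, eps = 1e-8) {
  nf <- sqrt(sum(fq^2) + eps^2)
  np <- sqrt(sum(p^2) + eps^2)
  alpha * sum(fq * p) / (nf * np)
}

oracle_alloc_pixel <- function(d) {
  s <- exp(d - max(d)); s <- s / sum(s)
  sum(d * s)
}

oracle_ce <- function(p_fg, p_bg, y, eps = 1e-7) {
  p_fg <- pmin(pmax(p_fg, eps), 1 - eps)
  p_bg <- pmin(pmax(p_bg, eps), 1 - eps)
  tot <- 0
  for (i in seq_along(y)) {
    tot <- tot - (y[i] * log(p_fg[i]) + (1 - y[i]) * log(p_bg[i]))
  }
  tot / length(y)
}

oracle_bce <- function(score, target, eps = 1e-7) {
  s <- min(max(score, eps), 1 - eps)
  -(target * log(s) + (1 - target) * log(1 - s))
}

oracle_dsc <- function(pred, truth) {
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(pred)) {
    inter <- inter + (pred[i] == 1 && truth[i] == 1)
    np <- np + (pred[i] == 1)
    nt <- nt + (truth[i] == 1)
  }
  if (np + nt == 0) return(100)
  200 * inter / (np + nt)
}

# ground-truth oracle predictor: looks the query slice up in the volume set
# and returns the true mask of the class annotated in the support
make_truth_predictor <- function(volumes) {
  function(si, sm, qi) {
    target <- NULL
    for (v in volumes) for (z in seq_len(dim(v$image)[3])) {
      if (isTRUE(all.equal(v$image[, , z], si, tolerance = 1e-12))) {
        cls <- v$labels[, , z][sm == 1]
        cls <- cls[cls != 0]
        target <- as.integer(names(sort(table(cls), decreasing = TRUE))[1])
      }
    }
    stopifnot(!is.null(target))
    for (v in volumes) for (z in seq_len(dim(v$image)[3])) {
      if (isTRUE(all.equal(v$image[, , z], qi, tolerance = 1e-12))) {
        return((v$labels[, , z] == target) * 1L)
      }
    }
    stop("query slice not found in volume set")
  }
}

# tiny deterministic episode on a structured image
toy_episode <- function(seed = 1, H = 16, W = 16) {
  withr::with_seed(seed, {
    img <- matrix(0.1 + 0.02 * stats::rnorm(H * W), H, W)
    img[4:9, 5:11] <- 0.8 + 0.02 * stats::rnorm(42)
    msk <- matrix(0, H, W); msk[4:9, 5:11] <- 1
    qimg <- matrix(0.1 + 0.02 * stats::rnorm(H * W), H, W)
    qimg[6:11, 4:10] <- 0.8 + 0.02 * stats::rnorm(42)
    qmsk <- matrix(0, H, W); qmsk[6:11, 4:10] <- 1
    episode(img, msk, qimg, qmsk, class_id = 1L)
  })
}

# small model configurations for fast tests
tiny_test_model <- function(seed = 1, fpn = TRUE, gnet = TRUE, oc = 8L) {
  protoseg_model(
    backbone = backbone_config("tiny_cnn", out_channels = oc, width = oc),
    fpn = if (fpn) fpn_config(n_scales = 2L, lateral_channels = 8L,
                              in_channels = 2L * oc + 1L) else NULL,
    gnet = if (gnet) discriminator_config(growth = 4L,
                                          head_hidden = c(8L, 4L)) else NULL,
    seed = seed)
}

# central finite-difference gradient of f at params[[nm]][i]
fd_grad <- function(f, params, nm, i, h = 1e-5) {
  p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
  p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
  (f(p2) - f(p3)) / (2 * h)
}
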