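# Prototype extraction, cosine-metric matching, allocation and prediction.
#
# These are the deterministic mathematical primitives of the segmentation
# network, defined on plain arrays so they can be verified against brute-force
# oracles independently of any learned backbone. Feature grids are arrays with
# dim c(H, W, Ch); masks are H x W matrices with values in [0, 1].

#' Tile a grid into non-overlapping pooling windows
#'
#' Windows have size `ceiling(window_scale * H)` by `ceiling(window_scale * W)`
#' and partition the grid with stride equal to the window size; edge windows
#' are truncated when the scale does not divide the grid evenly, and their
#' means are taken over the actual pixel count.
#'
#' @param H,W grid height and width.
#' @param window_scale fraction of each spatial dimension, in (0, 1].
#' @return list with `A`, an `(H*W) x K` column-stochastic averaging matrix
#'   (column k holds weight `1/n_k` on the pixels of window k), and `windows`,
#'   a data.frame of window row/col extents.
#' @keywords internal
window_partition <- function(H, W, window_scale) {
  stopifnot(window_scale > 0, window_scale <= 1)
  wh <- max(1L, ceiling(window_scale * H))
  ww <- max(1L, ceiling(window_scale * W))
  r0 <- seq.int(1L, H, by = wh)
  c0 <- seq.int(1L, W, by = ww)
  K <- length(r0) * length(c0)
  A <- matrix(0, H * W, K)
  wins <- vector("list", K)
  k <- 0L
  for (cj in c0) {
    for (ri in r0) {
      k <- k + 1L
      rr <- ri:min(ri + wh - 1L, H)
      cc <- cj:min(cj + ww - 1L, W)
      pix <- as.vector(outer(rr, (cc - 1L) * H, "+"))
      A[pix, k] <- 1 / length(pix)
      wins[[k]] <- c(r1 = rr[1], r2 = rr[length(rr)], c1 = cc[1], c2 = cc[length(cc)])
    }
  }
  list(A = A, windows = do.call(rbind, wins))
}

#' Masked average pooling: class-level global prototype
#'
#' The prototype is the mask-weighted spatial mean of the feature grid,
#' `sum_xy F(x,y) M(x,y) / sum_xy M(x,y)`, computed per channel.
#'
#' @param F_grid feature array, dim c(H, W, Ch).
#' @param M mask matrix (H x W), values in \[0, 1\], at least one positive.
#' @return numeric vector of length Ch.
#' @export
#' @examples
#' F_grid <- array(1:8, c(2, 2, 2))
#' M <- matrix(c(1, 0, 0, 0), 2, 2)
#' masked_global_prototype(F_grid, M)  # the (1,1) pixel's feature vector
masked_global_prototype <- function(F_grid, M) {
  stopifnot(length(dim(F_grid)) == 3L, all(dim(F_grid)[1:2] == dim(M)))
  s <- sum(M)
  if (s <= 0) stop("masked_global_prototype: mask has no positive pixel")
  d <- dim(F_grid)
  drop(crossprod(matrix(F_grid, d[1] * d[2], d[3]), c(M))) / s
}

#' Adaptive local prototypes by windowed average pooling
#'
#' The grid is tiled into non-overlapping pooling windows of size
#' `(window_scale * H, window_scale * W)`. Each window yields a candidate
#' prototype equal to the unweighted mean of the features over the window; a
#' window is kept when the mean of the mask over the window is at least `tau`.
#' When no window qualifies the set degenerates to the single masked-global
#' prototype (class-level fallback). Background prototype sets are obtained by
#' calling this function with the complement mask `1 - M`.
#'
#' @inheritParams masked_global_prototype
#' @param window_scale window size as a fraction of H and W, in (0, 1].
#' @param tau occupancy threshold in \[0, 1\]: minimum mask mean over a window
#'   for its prototype to count for the class. Default 0.95.
#' @param class_tag label stored with the set (e.g. "fg" or "bg").
#' @return an object of class `prototype_set`: list with `vectors` (K x Ch
#'   matrix), `kind` ("local" or "global" per prototype), `window` (window
#'   index or NA), `class_tag`, `window_scale`.
#' @export
local_prototypes <- function(F_grid, M, window_scale = 0.25, tau = 0.95,
                             class_tag = "fg") {
  stopifnot(length(dim(F_grid)) == 3L, all(dim(F_grid)[1:2] == dim(M)))
  if (sum(M) <= 0) {
    stop("local_prototypes: degenerate mask (no foreground pixel) for class ",
         class_tag)
  }
  d <- dim(F_grid)
  wp <- window_partition(d[1], d[2], window_scale)
  occ <- drop(crossprod(wp$A, c(M)))
  keep <- which(occ >= tau)
  if (length(keep) > 0L) {
    P <- crossprod(wp$A[, keep, drop = FALSE], matrix(F_grid, d[1] * d[2], d[3]))
    set <- list(vectors = P, kind = rep("local", length(keep)),
                window = keep, class_tag = class_tag,
                window_scale = window_scale)
  } else {
    P <- matrix(masked_global_prototype(F_grid, M), 1L, d[3])
    set <- list(vectors = P, kind = "global", window = NA_integer_,
                class_tag = class_tag, window_scale = window_scale)
  }
  class(set) <- "prototype_set"
  set
}

#' @export
print.prototype_set <- function(x, ...) {
  cat("<prototype_set>", nrow(x$vectors), "prototype(s),",
      ncol(x$vectors), "channels, class", x$class_tag,
      sprintf("(%s)\n", paste(unique(x$kind), collapse = "+")))
  invisible(x)
}

#' Scaled cosine similarity of query features against a prototype set
#'
#' For every query pixel and prototype k,
#' `D^k(x,y) = alpha_scale * cos(F_q(x,y), P_k)`. Norms are smoothed with a
#' small epsilon so zero-norm vectors give similarity 0 rather than NaN.
#'
#' @param F_q query feature array, dim c(H, W, Ch).
#' @param P a `prototype_set` (or plain K x Ch matrix).
#' @param alpha_scale similarity multiplier; default 20.
#' @param eps norm smoothing constant; default 1e-8.
#' @return object of class `similarity_stack`: list with `maps` (array
#'   H x W x K, each entry in \[-alpha_scale, alpha_scale\]) and `alpha_scale`.
#' @export
similarity_stack <- function(F_q, P, alpha_scale = 20, eps = 1e-8) {
  Pm <- if (inherits(P, "prototype_set")) P$vectors else P
  d <- dim(F_q)
  stopifnot(length(d) == 3L, ncol(Pm) == d[3])
  Fm <- matrix(F_q, d[1] * d[2], d[3])
  nf <- sqrt(rowSums(Fm^2) + eps^2)
  np <- sqrt(rowSums(Pm^2) + eps^2)
  Cm <- (Fm %*% t(Pm)) / outer(nf, np)
  out <- list(maps = array(alpha_scale * Cm, c(d[1], d[2], nrow(Pm))),
              alpha_scale = alpha_scale)
  class(out) <- "similarity_stack"
  out
}

#' Prototype allocation: fuse per-prototype similarity maps into one map
#'
#' At each pixel the K similarity values are combined by a softmax-weighted
#' average over the prototype axis:
#' `PM(x,y) = sum_k D^k(x,y) * softmax_k(D^k(x,y))`.
#' The result is a convex combination, so it always lies between the pixelwise
#' minimum and maximum similarity.
#'
#' @param S a `similarity_stack` (or plain H x W x K array).
#' @return H x W matrix.
#' @export
allocate_probability <- function(S) {
  D <- if (inherits(S, "similarity_stack")) S$maps else S
  d <- dim(D)
  if (is.na(d[3]) || d[3] < 1L) stop("allocate_probability: empty stack")
  Dm <- matrix(D, d[1] * d[2], d[3])
  e <- exp(Dm - apply(Dm, 1, max))
  W <- e / rowSums(e)
  matrix(rowSums(Dm * W), d[1], d[2])
}

#' Guide features: expand the pixelwise best prototype into a feature grid
#'
#' At each pixel the prototype with the maximal similarity is selected (ties
#' broken by the lowest prototype index) and its vector is placed at that
#' location.
#'
#' @inheritParams allocate_probability
#' @param P the `prototype_set` (or K x Ch matrix) the stack was computed from.
#' @return feature array, dim c(H, W, Ch).
#' @export
guide_features <- function(S, P) {
  D <- if (inherits(S, "similarity_stack")) S$maps else S
  Pm <- if (inherits(P, "prototype_set")) P$vectors else P
  d <- dim(D)
  stopifnot(d[3] == nrow(Pm))
  kstar <- max.col(matrix(D, d[1] * d[2], d[3]), ties.method = "first")
  array(Pm[kstar, , drop = FALSE], c(d[1], d[2], ncol(Pm)))
}

#' Merge guide features, foreground probability map and query features
#'
#' Concatenation along the channel axis in the order guide features,
#' probability plane, query features; the output has
#' `Ch(F_G) + 1 + Ch(F_q)` channels.
#'
#' @param F_G guide feature array (H, W, C1).
#' @param PM_fg foreground probability map (H x W).
#' @param F_q query feature array (H, W, C2).
#' @return array of dim c(H, W, C1 + 1 + C2).
#' @export
merge_features <- function(F_G, PM_fg, F_q) {
  d1 <- dim(F_G); d2 <- dim(F_q)
  if (!all(d1[1:2] == dim(PM_fg)) || !all(d1[1:2] == d2[1:2])) {
    stop("merge_features: spatial shapes disagree")
  }
  array(c(F_G, PM_fg, F_q), c(d1[1], d1[2], d1[3] + 1L + d2[3]))
}

#' Dump similarity maps and probability maps as a multi-page TIFF
#'
#' Inspection aid: each prototype's similarity map (rescaled from
#' \[-alpha, alpha\] to \[0, 1\]) becomes one page, followed by the
#' min-max-rescaled foreground and background probability maps.
#'
#' @param S a `similarity_stack`.
#' @param pm_fg,pm_bg probability maps from [allocate_probability()].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
write_debug_tiff <- function(S, pm_fg, pm_bg, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_debug_tiff requires the 'tiff' package")
  }
  a <- S$alpha_scale
  pages <- lapply(seq_len(dim(S$maps)[3]), function(k) {
    (S$maps[, , k] + a) / (2 * a)
  })
  rescale <- function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / diff(r) else m * 0
  }
  pages <- c(pages, list(rescale(pm_fg), rescale(pm_bg)))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Final binary prediction from foreground/background probability maps
#'
#' `mask(x,y) = 1` iff the foreground map strictly exceeds the background map;
#' ties go to background.
#'
#' @param pm_fg,pm_bg H x W score maps.
#' @return integer H x W matrix with values 0/1.
#' @export
final_prediction <- function(pm_fg, pm_bg) {
  stopifnot(all(dim(pm_fg) == dim(pm_bg)))
  m <- (pm_fg > pm_bg) * 1L
  dim(m) <- dim(pm_fg)
  m
}
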