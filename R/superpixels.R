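# Graph-based oversegmentation (Felzenszwalb-Huttenlocher) used to mint
# pseudo-labels for self-supervised episodes. Edges connect 4-neighbours,
# weighted by absolute intensity difference on the min-max normalised slice;
# components merge greedily in order of edge weight under the adaptive
# threshold min(Int(C) + k/|C|) and a final pass absorbs components smaller
# than min_size into their nearest neighbour. Implemented here because no
# installed R package provides this algorithm.

#' Oversegment a slice into superpixels
#'
#' Graph-based greedy merging on the 4-connected pixel lattice. The slice is
#' min-max normalised to \[0, 1\] first so `scale_param` has a consistent
#' meaning across modalities; larger values yield fewer, larger segments.
#'
#' @param image numeric matrix (one slice); all values must be finite.
#' @param scale_param merge-threshold constant k of the adaptive criterion
#'   (units of normalised intensity). Default 1.
#' @param min_size minimum segment size in pixels; smaller segments are merged
#'   into a neighbour. Default 30.
#' @return object of class `superpixel_map`: list with `labels` (integer
#'   matrix, contiguous ids `1..n_segments`), `n_segments`, `scale_param`,
#'   `min_size`.
#' @export
#' @examples
#' img <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
#' sp <- oversegment(img, scale_param = 0.1, min_size = 10)
#' sp$n_segments  # 2: one segment per homogeneous half
oversegment <- function(image, scale_param = 1, min_size = 30L) {
  if (!all(is.finite(image))) stop("oversegment: image has non-finite pixels")
  stopifnot(scale_param > 0, min_size >= 1L)
  H <- nrow(image); W <- ncol(image)
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
  n <- H * W
  # 4-connectivity edges: down and right neighbours.
  idx <- matrix(seq_len(n), H, W)
  a <- c(idx[-H, ], idx[, -W])
  b <- c(idx[-1, ], idx[, -1])
  w <- abs(img[a] - img[b])
  ord <- order(w)
  a <- a[ord]; b <- b[ord]; w <- w[ord]

  parent <- seq_len(n)
  size <- rep(1L, n)
  intd <- numeric(n)     # internal difference of each component root
  k <- scale_param
  # union-find with path halving; closure over `parent`
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(w)) {
    ra <- uf_find(a[e])
    rb <- uf_find(b[e])
    if (ra == rb) next
    we <- w[e]
    if (we <= intd[ra] + k / size[ra] && we <= intd[rb] + k / size[rb]) {
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
      intd[ra] <- we
    }
  }
  # Absorb undersized components, again in edge-weight order.
  for (e in seq_along(w)) {
    ra <- uf_find(a[e])
    rb <- uf_find(b[e])
    if (ra == rb) next
    if (size[ra] < min_size || size[rb] < min_size) {
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1))
  labels <- match(roots, unique(roots))
  out <- list(labels = matrix(as.integer(labels), H, W),
              n_segments = length(unique(labels)),
              scale_param = scale_param, min_size = as.integer(min_size))
  class(out) <- "superpixel_map"
  out
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat("<superpixel_map>", paste(dim(x$labels), collapse = " x "), "pixels,",
      x$n_segments, "segments (k =", x$scale_param,
      ", min_size =", x$min_size, ")\n")
  invisible(x)
}
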