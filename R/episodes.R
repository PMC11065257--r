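# Self-supervised episodes: a superpixel of a slice is promoted to a
# pseudo-foreground mask (the support), and a geometrically + photometrically
# transformed view of the same slice forms the query. This supplies the
# annotation-free 1-way 1-shot training signal.

#' Augmentation parameter ranges for pseudo-episodes
#'
#' The geometric component (rotation, isotropic scale, shear, translation) is
#' applied identically to image and mask; the intensity component (gamma) is
#' applied to the image only.
#'
#' @param rotation maximum absolute rotation, degrees.
#' @param scale length-2 isotropic scale factor range.
#' @param shear maximum absolute shear, degrees.
#' @param translate maximum absolute translation, as a fraction of each
#'   spatial dimension.
#' @param gamma length-2 gamma-correction exponent range.
#' @return object of class `aug_params`.
#' @export
aug_params <- function(rotation = 30, scale = c(0.9, 1.1), shear = 10,
                       translate = 0.1, gamma = c(0.7, 1.5)) {
  out <- list(rotation = rotation, scale = scale, shear = shear,
              translate = translate, gamma = gamma)
  class(out) <- "aug_params"
  out
}

#' Identity transform parameters
#' @return a transform parameter list leaving inputs unchanged.
#' @export
identity_transform <- function() {
  list(angle = 0, scale = 1, shear = 0, dy = 0, dx = 0, gamma = 1)
}

# Draw one concrete transform from the ranges. Must be called inside a
# seeded RNG context.
sample_transform <- function(aug, H, W) {
  list(angle = stats::runif(1, -aug$rotation, aug$rotation),
       scale = stats::runif(1, aug$scale[1], aug$scale[2]),
       shear = stats::runif(1, -aug$shear, aug$shear),
       dy = stats::runif(1, -aug$translate, aug$translate) * H,
       dx = stats::runif(1, -aug$translate, aug$translate) * W,
       gamma = stats::runif(1, aug$gamma[1], aug$gamma[2]))
}

# Forward 2x2 affine matrix: scale %*% shear %*% rotation.
affine_matrix <- function(params) {
  th <- params$angle * pi / 180
  sh <- tan(params$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  params$scale * (S %*% R)
}

#' Apply a recorded transform identically to an image and its mask
#'
#' Geometric warping (rotation, scale, shear about the slice center, then
#' translation) uses inverse mapping with bilinear interpolation for the
#' image and nearest-neighbour for the mask, so the mask stays binary. The
#' gamma exponent is applied to the image only. Out-of-frame samples are 0.
#'
#' Accepted parameter ranges: `|angle| <= 180`, `scale` in \[0.5, 2\],
#' `|shear| <= 45`, `gamma` in \[0.2, 5\].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param mask binary matrix of the same shape.
#' @param params transform parameter list as produced internally from
#'   [aug_params()] or by [identity_transform()]: fields `angle`, `scale`,
#'   `shear`, `dy`, `dx`, `gamma`.
#' @return list with `image` and `mask`, same shapes as the inputs.
#' @export
transform_pair <- function(image, mask, params) {
  stopifnot(all(dim(image) == dim(mask)))
  if (abs(params$angle) > 180 || params$scale < 0.5 || params$scale > 2 ||
      abs(params$shear) > 45 || params$gamma < 0.2 || params$gamma > 5) {
    stop("transform_pair: parameters outside declared ranges")
  }
  H <- nrow(image); W <- ncol(image)
  if (identical(params[c("angle", "scale", "shear", "dy", "dx")],
                identity_transform()[c("angle", "scale", "shear", "dy", "dx")])) {
    img <- if (params$gamma == 1) image else pmax(image, 0)^params$gamma
    return(list(image = img, mask = mask))
  }
  A <- affine_matrix(params)
  Ainv <- solve(A)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  # output pixel coordinates, centered, translation removed
  oy <- matrix(seq_len(H), H, W) - cy - params$dy
  ox <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - params$dx
  sy <- Ainv[1, 1] * oy + Ainv[1, 2] * ox + cy
  sx <- Ainv[2, 1] * oy + Ainv[2, 2] * ox + cx
  img <- bilinear_sample(image, sy, sx)
  msk <- nearest_sample(mask, sy, sx)
  img <- if (params$gamma == 1) img else pmax(img, 0)^params$gamma
  list(image = img, mask = msk)
}

bilinear_sample <- function(m, sy, sx) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * get(y0, x0) +
       (1 - fy) * fx * get(y0, x0 + 1) +
       fy * (1 - fx) * get(y0 + 1, x0) +
       fy * fx * get(y0 + 1, x0 + 1)
  matrix(v, nrow(sy), ncol(sy))
}

# Absolute difference between a segment's mean intensity and the mean over
# a 2-pixel ring around it.
segment_contrast <- function(image, mask) {
  dil <- mask
  for (rep in 1:2) {
    d <- dil
    d[-1, ] <- d[-1, ] | dil[-nrow(dil), ]
    d[-nrow(d), ] <- d[-nrow(d), ] | dil[-1, ]
    d[, -1] <- d[, -1] | dil[, -ncol(dil)]
    d[, -ncol(d)] <- d[, -ncol(d)] | dil[, -1]
    dil <- d
  }
  ring <- dil & !mask
  if (!any(ring)) return(Inf)
  abs(mean(image[mask]) - mean(image[ring]))
}

# Bilinear upsampling by integer factor with edge clamping (used to bring
# feature-resolution score maps back to image resolution).
upsample_bilinear <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  sy <- pmin(pmax((seq_len(H * f) - 0.5) / f + 0.5, 1), H)
  sx <- pmin(pmax((seq_len(W * f) - 0.5) / f + 0.5, 1), W)
  SY <- matrix(sy, H * f, W * f)
  SX <- matrix(sx, H * f, W * f, byrow = TRUE)
  bilinear_sample(m, SY, SX)
}

nearest_sample <- function(m, sy, sx) {
  H <- nrow(m); W <- ncol(m)
  yy <- round(sy); xx <- round(sx)
  ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
  v <- numeric(length(yy))
  v[ok] <- m[cbind(yy[ok], xx[ok])]
  matrix(v, H, W)
}

#' Build a pseudo-labelled episode from a slice and its superpixel map
#'
#' One superpixel whose pixel count falls inside the eligible size band is
#' drawn uniformly and promoted to the support foreground mask; the query is
#' a transformed view of the same slice with the identically transformed
#' mask. Deterministic given `seed`.
#'
#' @param image numeric slice matrix.
#' @param superpixels a [oversegment()] result aligned with `image`.
#' @param aug an [aug_params()] object, or `NULL` for the identity transform.
#' @param seed integer seed for segment choice and transform draw.
#' @param size_band eligible segment size band in pixels at 256 x 256,
#'   rescaled by area for other slice sizes. Default c(100, 2000).
#' @param min_contrast minimum absolute difference between the mean intensity
#'   inside a segment and in a 2-pixel ring around it for the segment to be
#'   promoted to a pseudo-label. A segment indistinguishable from its
#'   surroundings defines an unlearnable episode whose only optimum is total
#'   uncertainty, which drags the feature space toward collapse; the default
#'   0.08 sits just under the minimum class-intensity separation (0.1) and
#'   above typical noise. Set to 0 to disable.
#' @return object of class `protoseg_episode`: list with `support_image`,
#'   `support_mask`, `query_image`, `query_mask`, `class_id` (superpixel id),
#'   `provenance = "pseudo"` and the recorded `transform`.
#' @export
make_pseudo_episode <- function(image, superpixels, aug = aug_params(),
                                seed = 1L, size_band = c(100, 2000),
                                min_contrast = 0.08) {
  stopifnot(inherits(superpixels, "superpixel_map"),
            all(dim(image) == dim(superpixels$labels)))
  H <- nrow(image); W <- ncol(image)
  band <- size_band * (H * W) / (256 * 256)
  counts <- tabulate(superpixels$labels, nbins = superpixels$n_segments)
  eligible <- which(counts >= band[1] & counts <= band[2])
  if (length(eligible) == 0L) {
    stop("make_pseudo_episode: no superpixel within the size band [",
         round(band[1]), ", ", round(band[2]), "] px")
  }
  if (min_contrast > 0) {
    eligible <- eligible[vapply(eligible, function(id) {
      segment_contrast(image, superpixels$labels == id) >= min_contrast
    }, logical(1))]
    if (length(eligible) == 0L) {
      stop("make_pseudo_episode: no size-eligible superpixel with contrast >= ",
           min_contrast)
    }
  }
  withr::with_seed(seed, {
    id <- eligible[sample.int(length(eligible), 1L)]
    mask <- (superpixels$labels == id) * 1
    params <- if (is.null(aug)) identity_transform() else
      sample_transform(aug, H, W)
    tq <- transform_pair(image, mask, params)
    out <- list(support_image = image, support_mask = mask,
                query_image = tq$image, query_mask = tq$mask,
                class_id = id, provenance = "pseudo", transform = params)
    class(out) <- "protoseg_episode"
    out
  })
}

#' Construct an episode from labelled data
#'
#' @param support_image,support_mask,query_image,query_mask equal-shape
#'   matrices; masks binary with at least one support foreground pixel.
#' @param class_id integer class id.
#' @return object of class `protoseg_episode` with `provenance = "real"`.
#' @export
episode <- function(support_image, support_mask, query_image, query_mask,
                    class_id = 1L) {
  stopifnot(all(dim(support_image) == dim(support_mask)),
            all(dim(query_image) == dim(query_mask)),
            all(support_mask %in% c(0, 1)), sum(support_mask) >= 1)
  out <- list(support_image = support_image, support_mask = support_mask,
              query_image = query_image, query_mask = query_mask,
              class_id = as.integer(class_id), provenance = "real",
              transform = NULL)
  class(out) <- "protoseg_episode"
  out
}

#' Cache episodes on disk
#'
#' Each episode is stored as one archive (images and masks plus the recorded
#' transform) with a JSON index of metadata for the whole directory.
#'
#' @param episodes list of `protoseg_episode` objects.
#' @param dir target directory (created if missing).
#' @return invisibly, the index path.
#' @export
write_episodes <- function(episodes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list()
  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    f <- sprintf("episode_%04d.rds", i)
    saveRDS(ep, file.path(dir, f))
    meta[[i]] <- list(file = f, class_id = ep$class_id,
                      provenance = ep$provenance,
                      fg_pixels = sum(ep$support_mask))
  }
  idx <- file.path(dir, "index.json")
  jsonlite::write_json(meta, idx, auto_unbox = TRUE, digits = NA)
  invisible(idx)
}

#' Read a cached episode directory
#' @param dir directory written by [write_episodes()].
#' @return list of `protoseg_episode` objects.
#' @export
read_episodes <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  lapply(idx, function(m) readRDS(file.path(dir, m$file)))
}

#' @export
print.protoseg_episode <- function(x, ...) {
  cat("<protoseg_episode>", paste(dim(x$support_image), collapse = " x "),
      "| class", x$class_id, "|", x$provenance,
      "| fg", sum(x$support_mask), "px\n")
  invisible(x)
}
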