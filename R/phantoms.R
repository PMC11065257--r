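# Synthetic phantom volumes: stacks of 2-D slices containing a handful of
# disjoint "organ" classes rendered as simple geometric shapes with distinct
# intensities, plus additive Gaussian noise. They emulate the small-foreground
# / large-background imbalance of abdominal scans at desk scale and make every
# downstream stage (self-supervision, episodic training, unseen-class
# evaluation) runnable with no external data.

#' Specification of a synthetic phantom volume
#'
#' @param grid_size integer vector `(H, W, depth)` in voxels.
#' @param classes list of class descriptors, each a list with `shape` (one of
#'   `"disk"`, `"ellipse"`, `"ring"`, `"crescent"`), `intensity` (mean in
#'   \[0,1\]) and `size` (length-2 in-plane radius range as a fraction of the
#'   smaller slice dimension, each in (0, 0.5\]). Intensity means must be
#'   pairwise at least 0.1 apart so classes stay learnable.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param background background intensity.
#' @param n_distractors number of unlabelled background structures (random
#'   blobs of varying intensity, label 0). Real scans carry abundant
#'   structure outside the organs of interest, and that structure is what
#'   makes superpixel pseudo-labels a meaningful training signal; a uniform
#'   background would make most pseudo-labels arbitrary noise partitions.
#' @param distractor_intensity intensity range of distractor structures.
#' @param distractor_size in-plane radius fraction range of distractors.
#' @param seed integer seed driving shape placement and noise.
#' @return object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec()
#' vol <- generate_volume(spec)
#' table(vol$labels)
phantom_spec <- function(grid_size = c(64L, 64L, 24L),
                         classes = default_phantom_classes(),
                         noise_sigma = 0.02,
                         background = 0.05,
                         n_distractors = 8L,
                         distractor_intensity = c(0.15, 0.95),
                         distractor_size = c(0.05, 0.11),
                         seed = 1L) {
  stopifnot(length(grid_size) == 3L, all(grid_size >= 1L))
  if (grid_size[3] < 5L) stop("phantom_spec: depth must be at least 5 slices")
  ints <- vapply(classes, function(cl) cl$intensity, numeric(1))
  if (length(ints) > 1L && min(stats::dist(ints)) < 0.1) {
    stop("phantom_spec: class intensity means must be pairwise >= 0.1 apart")
  }
  for (cl in classes) {
    if (!cl$shape %in% c("disk", "ellipse", "ring", "crescent")) {
      stop("phantom_spec: unknown shape family '", cl$shape, "'")
    }
    if (any(cl$size <= 0) || any(cl$size > 0.5)) {
      stop("phantom_spec: size fractions must lie in (0, 0.5]")
    }
  }
  out <- list(grid_size = as.integer(grid_size), classes = classes,
              noise_sigma = noise_sigma, background = background,
              n_distractors = as.integer(n_distractors),
              distractor_intensity = distractor_intensity,
              distractor_size = distractor_size,
              seed = as.integer(seed))
  class(out) <- "phantom_spec"
  out
}

#' Default phantom class descriptors
#'
#' Four shape families at well-separated intensities; radius fractions keep
#' every per-slice foreground fraction within the small-organ band.
#' @return list of class descriptors for [phantom_spec()].
#' @export
default_phantom_classes <- function() {
  list(
    list(shape = "disk",     intensity = 0.85, size = c(0.13, 0.22)),
    list(shape = "ellipse",  intensity = 0.65, size = c(0.13, 0.22)),
    list(shape = "ring",     intensity = 0.45, size = c(0.15, 0.24)),
    list(shape = "crescent", intensity = 0.25, size = c(0.15, 0.24))
  )
}

# Rasterize one shape on an H x W slice; returns a logical matrix.
# r is the in-plane radius in pixels, ang a fixed orientation (radians).
rasterize_shape <- function(shape, H, W, cy, cx, r, ang = 0) {
  y <- matrix(seq_len(H), H, W) - cy
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <-  cos(ang) * y + sin(ang) * x
  v <- -sin(ang) * y + cos(ang) * x
  switch(shape,
    disk = (u^2 + v^2) <= r^2,
    ellipse = (u / r)^2 + (v / (0.6 * r))^2 <= 1,
    ring = {
      q <- u^2 + v^2
      q <= r^2 & q >= (0.55 * r)^2
    },
    crescent = {
      main <- (u^2 + v^2) <= r^2
      bite <- ((u - 0.55 * r)^2 + v^2) <= (0.8 * r)^2
      main & !bite
    },
    stop("unknown shape: ", shape))
}

#' Generate a synthetic phantom volume
#'
#' Each class is placed as a 3-D connected blob: a fixed in-plane center with
#' a smooth per-slice radius profile over at least 3 consecutive slices.
#' Classes never overlap; placement is retried and an error is raised when no
#' disjoint placement can be found. With `noise_sigma = 0` the image is
#' exactly piecewise constant (background value outside, the class intensity
#' inside). Per-slice foreground fractions stay within \[0.5%, 30%\].
#'
#' @param spec a [phantom_spec()].
#' @param max_retries placement retries per class before failing.
#' @return object of class `phantom_volume`: list with `image` (H x W x depth
#'   array in \[0,1\]), `labels` (integer array, 0 = background, k = class k)
#'   and `spec`.
#' @export
generate_volume <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_size
  H <- g[1]; W <- g[2]; D <- g[3]
  withr::with_seed(spec$seed, {
    labels <- array(0L, c(H, W, D))
    occupied <- array(FALSE, c(H, W, D))
    shapes <- c("disk", "ellipse", "ring", "crescent")
    # try to place one 3-D blob; returns slice masks or NULL
    try_place <- function(shape, r, frac_lo) {
      nzv <- min(5L, D):min(9L, D)
      nz <- nzv[sample.int(length(nzv), 1L)]
      z0 <- sample.int(D - nz + 1L, 1L)
      cy <- stats::runif(1, r + 2, H - r - 1)
      cx <- stats::runif(1, r + 2, W - r - 1)
      ang <- stats::runif(1, 0, pi)
      u <- seq(-0.9, 0.9, length.out = nz)
      prof <- pmax(sqrt(1 - u^2), 0.5)
      cand <- vector("list", nz)
      for (j in seq_len(nz)) {
        m <- rasterize_shape(shape, H, W, cy, cx, r * prof[j], ang)
        frac <- sum(m) / (H * W)
        if (frac < frac_lo || frac > 0.30 ||
            any(occupied[, , z0 + j - 1L][m])) {
          return(NULL)
        }
        cand[[j]] <- m
      }
      list(z0 = z0, masks = cand)
    }
    for (k in seq_along(spec$classes)) {
      cl <- spec$classes[[k]]
      placed <- NULL
      for (try in seq_len(max_retries)) {
        r <- stats::runif(1, cl$size[1], cl$size[2]) * min(H, W)
        placed <- try_place(cl$shape, r, frac_lo = 0.005)
        if (!is.null(placed)) break
      }
      if (is.null(placed)) {
        stop("generate_volume: could not place class ", k, " (", cl$shape,
             ") without overlap after ", max_retries, " retries; spec: grid ",
             paste(g, collapse = "x"), ", ", length(spec$classes), " classes")
      }
      for (j in seq_along(placed$masks)) {
        z <- placed$z0 + j - 1L
        sl <- labels[, , z]
        sl[placed$masks[[j]]] <- k
        labels[, , z] <- sl
        occupied[, , z] <- occupied[, , z] | placed$masks[[j]]
      }
    }
    # unlabelled background structures (superpixel sources for SSL); a
    # failed placement is simply skipped
    distract <- array(NA_real_, c(H, W, D))
    class_ints <- vapply(spec$classes, function(cl) cl$intensity, numeric(1))
    for (k in seq_len(spec$n_distractors)) {
      # keep distractor intensities separated from every labelled class,
      # mirroring the pairwise-distinct constraint on class intensities:
      # one-shot matching on intensity phantoms is ill-posed against
      # unlabelled metamers of the target class
      iv <- 0
      for (draw in 1:50) {
        iv <- stats::runif(1, spec$distractor_intensity[1],
                           spec$distractor_intensity[2])
        if (all(abs(iv - class_ints) >= 0.08)) break
      }
      placed <- NULL
      for (try in seq_len(max_retries)) {
        r <- stats::runif(1, spec$distractor_size[1],
                          spec$distractor_size[2]) * min(H, W)
        placed <- try_place(shapes[sample.int(4L, 1L)], r, frac_lo = 0)
        if (!is.null(placed)) break
      }
      if (is.null(placed)) next
      for (j in seq_along(placed$masks)) {
        z <- placed$z0 + j - 1L
        sl <- distract[, , z]
        sl[placed$masks[[j]]] <- iv
        distract[, , z] <- sl
        occupied[, , z] <- occupied[, , z] | placed$masks[[j]]
      }
    }
    image <- array(spec$background, c(H, W, D))
    image[!is.na(distract)] <- distract[!is.na(distract)]
    for (k in seq_along(spec$classes)) {
      image[labels == k] <- spec$classes[[k]]$intensity
    }
    if (spec$noise_sigma > 0) {
      image <- image + stats::rnorm(length(image), 0, spec$noise_sigma)
      image <- pmin(pmax(image, 0), 1)
    }
    out <- list(image = image, labels = labels, spec = spec)
    class(out) <- "phantom_volume"
    out
  })
}

#' @export
print.phantom_volume <- function(x, ...) {
  g <- x$spec$grid_size
  cat("<phantom_volume>", paste(g, collapse = " x "), "voxels,",
      length(x$spec$classes), "classes, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Split class ids into train and test sets by fold
#'
#' Sorted ids are partitioned into `n_folds` contiguous blocks of (near)
#' equal size; block `fold` is the held-out test set and the remaining ids
#' form the training set. Folds are 1-based.
#'
#' @param class_ids vector of class ids.
#' @param n_folds number of folds (>= 2).
#' @param fold which fold to hold out, in `1..n_folds`.
#' @return list with `train` and `test` id vectors.
#' @export
#' @examples
#' split_classes(1:4, n_folds = 2, fold = 1)  # test 1,2 / train 3,4
split_classes <- function(class_ids, n_folds, fold) {
  stopifnot(n_folds >= 2L, length(class_ids) >= n_folds)
  if (fold < 1L || fold > n_folds) {
    stop("split_classes: fold must be in 1..", n_folds)
  }
  ids <- sort(class_ids)
  block <- ceiling(seq_along(ids) * n_folds / length(ids))
  list(train = ids[block != fold], test = ids[block == fold])
}

#' Slice indices free of the given classes
#'
#' Used to eliminate from the training stream every slice that contains a
#' held-out test class.
#'
#' @param volume a `phantom_volume` (or integer label array).
#' @param exclude_classes class ids that must not appear.
#' @return integer vector of usable slice indices.
#' @export
training_slices <- function(volume, exclude_classes) {
  labels <- if (inherits(volume, "phantom_volume")) volume$labels else volume
  D <- dim(labels)[3]
  keep <- vapply(seq_len(D), function(z) {
    !any(labels[, , z] %in% exclude_classes)
  }, logical(1))
  which(keep)
}

#' Write a phantom volume as NIfTI image/label files plus a JSON sidecar
#'
#' @param volume a `phantom_volume`.
#' @param dir output directory (created if missing).
#' @param name file stem; writes `<name>_image.nii.gz`,
#'   `<name>_labels.nii.gz`, `<name>_spec.json`.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(volume, dir, name = "phantom") {
  stopifnot(inherits(volume, "phantom_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_img <- file.path(dir, paste0(name, "_image.nii.gz"))
  p_lab <- file.path(dir, paste0(name, "_labels.nii.gz"))
  p_json <- file.path(dir, paste0(name, "_spec.json"))
  RNifti::writeNifti(volume$image, p_img)
  RNifti::writeNifti(volume$labels, p_lab)
  spec <- volume$spec
  jsonlite::write_json(
    list(grid_size = spec$grid_size,
         classes = spec$classes,
         noise_sigma = spec$noise_sigma,
         background = spec$background,
         seed = spec$seed),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, labels = p_lab, spec = p_json))
}
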