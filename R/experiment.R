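# Desk-scale end-to-end experiment: synthetic phantom volumes, superpixel
# self-supervision with held-out-class slice elimination, episodic training
# of the chosen model variant, and unseen-class 1-way 1-shot evaluation under
# the volumetric chunk-pairing protocol.

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1009 + salt) %% 2147483579)
}

#' Generate the phantom volume set used by the desk experiment
#'
#' @param n_volumes number of volumes.
#' @param seed base seed; each volume gets a derived seed.
#' @param noise_sigma additive noise level.
#' @param grid_size voxel grid per volume.
#' @return list of `phantom_volume` objects.
#' @export
desk_phantom_set <- function(n_volumes = 3L, seed = 1L, noise_sigma = 0.02,
                             grid_size = c(64L, 64L, 24L)) {
  lapply(seq_len(n_volumes), function(v) {
    generate_volume(phantom_spec(grid_size = grid_size,
                                 noise_sigma = noise_sigma,
                                 seed = derive_seed(seed, 7 * v)))
  })
}

#' Self-supervised episode stream over phantom volumes
#'
#' Draws a slice uniformly from the allowed (test-class-free) slices of a
#' random volume, oversegments it (memoised per slice), and promotes a
#' random size-eligible superpixel to a pseudo-labelled episode with an
#' augmented query view. Deterministic in `(seed, iteration)`.
#'
#' @param volumes list of `phantom_volume` objects.
#' @param exclude_classes classes whose slices are eliminated from training.
#' @param seed stream seed.
#' @param aug an [aug_params()].
#' @param scale_param,min_size oversegmentation parameters.
#' @param size_band eligible superpixel size band (pixels at 256 x 256).
#' @param min_contrast minimum segment-versus-surroundings intensity
#'   contrast for a pseudo-label (see [make_pseudo_episode()]).
#' @return function `(iteration) -> protoseg_episode`.
#' @export
ssl_stream <- function(volumes, exclude_classes = integer(0), seed = 1L,
                       aug = aug_params(), scale_param = 0.5, min_size = 16L,
                       size_band = c(100, 8000), min_contrast = 0.08) {
  allowed <- lapply(volumes, training_slices, exclude_classes = exclude_classes)
  keep <- which(vapply(allowed, length, integer(1)) > 0L)
  if (length(keep) == 0L) stop("ssl_stream: no usable training slices")
  cache <- new.env(parent = emptyenv())
  function(it) {
    for (attempt in 0:9) {
      drawn <- withr::with_seed(derive_seed(seed, 131 * it + attempt), {
        v <- keep[sample.int(length(keep), 1L)]
        z <- allowed[[v]][sample.int(length(allowed[[v]]), 1L)]
        list(v = v, z = z)
      })
      key <- paste(drawn$v, drawn$z, sep = "_")
      sp <- cache[[key]]
      img <- volumes[[drawn$v]]$image[, , drawn$z]
      if (is.null(sp)) {
        sp <- oversegment(img, scale_param = scale_param, min_size = min_size)
        cache[[key]] <- sp
      }
      ep <- tryCatch(
        make_pseudo_episode(img, sp, aug = aug,
                            seed = derive_seed(seed, 131 * it + attempt + 17L),
                            size_band = size_band,
                            min_contrast = min_contrast),
        error = function(e) NULL)
      if (!is.null(ep)) return(ep)
    }
    stop("ssl_stream: no eligible superpixel found after 10 slice draws")
  }
}

#' Run one desk-scale few-shot experiment
#'
#' Trains the requested model variant from scratch on superpixel
#' pseudo-episodes drawn from phantom volumes (slices containing the held-out
#' class are eliminated), then evaluates 1-way 1-shot segmentation of the
#' held-out class with the chunk-pairing protocol, alongside the untrained
#' same-initialisation baseline.
#'
#' Variants: `"alloc"` trains the prototype-allocation branch alone;
#' `"multiscale"` adds the multi-scale auxiliary head; `"adversarial"` additionally
#' trains the adversarial mask-quality discriminator.
#'
#' @param seed experiment seed (volumes, initialisation, episode stream).
#' @param variant one of `"adversarial"`, `"multiscale"`, `"alloc"`.
#' @param fold which class fold to hold out (1..4 with default phantoms).
#' @param epochs,episodes_per_epoch training schedule (defaults give 600
#'   episodes).
#' @param lr initial learning rate for the from-scratch desk run (the
#'   full-scale protocol value 0.001 assumes a pretrained backbone and a
#'   long schedule; a tiny network trained from scratch for a few hundred
#'   episodes needs a larger step).
#' @param clip gradient-norm clip for the desk run.
#' @param decay per-epoch learning-rate decay.
#' @param weights a [loss_weights()].
#' @param n_volumes phantom volumes to generate.
#' @param noise_sigma phantom noise level.
#' @param out_channels backbone feature channels.
#' @param gnet_growth dense-block growth of the desk-scale discriminator.
#' @param size_band pseudo-label size band (pixels at 256 x 256); the desk
#'   default extends the upper end so pseudo-labels span the size range of
#'   the phantom organs being evaluated.
#' @param n_chunks evaluation chunk count.
#' @param verbose print training progress.
#' @return list with `variant`, `seed`, `test_class`, `dsc_trained`,
#'   `dsc_untrained`, `model`, `eval_trained`, `eval_untrained`.
#' @export
desk_experiment <- function(seed = 1L, variant = c("adversarial", "multiscale", "alloc"),
                            fold = 1L, epochs = 4L, episodes_per_epoch = 150L,
                            lr = 0.01, clip = 3, decay = 0.98,
                            weights = loss_weights(), n_volumes = 3L,
                            noise_sigma = 0.02, out_channels = 16L,
                            gnet_growth = 8L, size_band = c(100, 8000),
                            n_chunks = 9L, verbose = FALSE) {
  variant <- match.arg(variant)
  volumes <- desk_phantom_set(n_volumes, seed, noise_sigma)
  n_classes <- length(volumes[[1]]$spec$classes)
  sp <- split_classes(seq_len(n_classes), n_folds = n_classes, fold = fold)
  bb <- backbone_config("tiny_cnn", out_channels = out_channels)
  fpn <- if (variant %in% c("multiscale", "adversarial")) {
    fpn_config(in_channels = 2L * bb$out_channels + 1L)
  } else NULL
  gnet <- if (variant == "adversarial") {
    discriminator_config(growth = gnet_growth)
  } else NULL
  model <- protoseg_model(backbone = bb, fpn = fpn, gnet = gnet,
                          seed = derive_seed(seed, 23))
  model$train_classes <- sp$train
  stream <- ssl_stream(volumes, exclude_classes = sp$test,
                       seed = derive_seed(seed, 41), size_band = size_band)
  ev_un <- suppressWarnings(
    evaluate_model(model, volumes, sp$test, n_chunks, fold = fold))
  cfg <- train_config(epochs = epochs,
                      episodes_per_epoch = episodes_per_epoch,
                      lr0 = lr, clip = clip, decay = decay, weights = weights,
                      seed = derive_seed(seed, 59))
  trained <- train_protoseg(model, stream, cfg, verbose = verbose)
  ev_tr <- suppressWarnings(
    evaluate_model(trained, volumes, sp$test, n_chunks, fold = fold))
  list(variant = variant, seed = seed, test_class = sp$test,
       dsc_trained = ev_tr$mean_dsc, dsc_untrained = ev_un$mean_dsc,
       model = trained, eval_trained = ev_tr, eval_untrained = ev_un)
}

#' Run the desk experiment over several seeds and variants
#'
#' @param seeds integer vector of experiment seeds.
#' @param variants variants to run (see [desk_experiment()]).
#' @param ... passed to [desk_experiment()].
#' @return data.frame with one row per (variant, seed): trained and
#'   untrained mean unseen-class DSC.
#' @export
desk_experiment_grid <- function(seeds = 1:3,
                                 variants = c("alloc", "multiscale", "adversarial"),
                                 ...) {
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      r <- desk_experiment(seed = s, variant = v, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = s, dsc_trained = r$dsc_trained,
        dsc_untrained = r$dsc_untrained)
    }
  }
  do.call(rbind, rows)
}
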