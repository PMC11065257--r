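# Alternating episodic training: one SGD step on the generator objective,
# then one on the discriminator objective, per episode. Learning rate decays
# geometrically per epoch; SGD uses momentum 0.9 and no weight decay.

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param episodes_per_epoch episodes drawn per epoch.
#' @param lr0 initial learning rate (the full-scale training protocol uses
#'   0.001; desk-scale from-scratch runs use a larger value, see
#'   [desk_experiment()]).
#' @param decay per-epoch multiplicative learning-rate decay.
#' @param momentum SGD momentum.
#' @param clip global gradient-norm clip applied per step (`Inf` disables).
#'   Training from a random initialisation is sensitive to occasional large
#'   episode gradients; clipping keeps early steps bounded.
#' @param weights a [loss_weights()].
#' @param seed integer seed controlling the episode stream and any remaining
#'   stochasticity.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 5L, episodes_per_epoch = 100L,
                         lr0 = 0.001, decay = 0.98, momentum = 0.9,
                         clip = 1, weights = loss_weights(), seed = 1L) {
  out <- list(epochs = as.integer(epochs),
              episodes_per_epoch = as.integer(episodes_per_epoch),
              lr0 = lr0, decay = decay, momentum = momentum, clip = clip,
              weights = weights, seed = as.integer(seed))
  class(out) <- "train_config"
  out
}

#' Learning rate after a given number of completed epochs
#' @param lr0 initial rate.
#' @param decay per-epoch decay factor.
#' @param epoch number of completed epochs.
#' @return `lr0 * decay^epoch`.
#' @export
lr_schedule <- function(lr0, decay, epoch) lr0 * decay^epoch

sgd_step <- function(params, grads, velocity, lr, momentum, clip = Inf) {
  if (is.finite(clip)) {
    total <- sqrt(sum(vapply(grads, function(g) {
      if (is.null(g)) 0 else sum(g^2)
    }, numeric(1))))
    if (total > clip) grads <- lapply(grads, function(g) {
      if (is.null(g)) NULL else g * (clip / total)
    })
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- momentum * velocity[[nm]] - lr * g
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

#' Train a few-shot segmentation model on an episode stream
#'
#' Each iteration draws one episode, takes a generator step on the composite
#' objective (prototype cross-entropy + alignment + weighted multi-scale
#' loss + weighted adversarial reward), then a discriminator step on the
#' mask-quality objective with the generator's prediction detached. The
#' learning rate for epoch e (1-based) is `lr0 * decay^(e-1)`. Runs are
#' deterministic given the configuration seed.
#'
#' @param model a [protoseg_model()].
#' @param stream function `(iteration) -> protoseg_episode`, deterministic in
#'   its argument, or a list of episodes recycled as needed.
#' @param cfg a [train_config()].
#' @param checkpoint_dir optional directory; when set, weights are saved per
#'   epoch as RDS files.
#' @param verbose print per-epoch metrics.
#' @return the trained model; `$metrics` holds a per-epoch data.frame (loss
#'   components, mean train Dice, alignment skips, learning rate) and
#'   `$iter_log` the per-iteration totals.
#' @export
train_protoseg <- function(model, stream, cfg = train_config(),
                           checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "protoseg_model"))
  get_episode <- if (is.function(stream)) stream else {
    function(i) stream[[((i - 1L) %% length(stream)) + 1L]]
  }
  gen <- model$params$gen
  disc <- model$params$disc
  use_disc <- !is.null(disc) && !is.null(model$gnet)
  v_gen <- zero_like(gen)
  v_disc <- if (use_disc) zero_like(disc) else NULL
  metrics <- vector("list", cfg$epochs)
  iter_log <- numeric(0)
  it <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(cfg$lr0, cfg$decay, epoch - 1L)
    acc <- c(l_pro = 0, l_align = 0, l_fpn = 0, l_adv = 0, total = 0,
             l_disc = 0, dsc = 0)
    n_align <- 0L
    skips <- 0L
    for (i in seq_len(cfg$episodes_per_epoch)) {
      it <- it + 1L
      ep <- get_episode(it)
      # generator step
      tape <- ag_tape()
      pn <- ag_leaves(tape, gen)
      obj <- generator_objective(tape, pn, ep, model, cfg$weights,
                                 disc_params = if (use_disc) disc else NULL)
      if (!is.finite(obj$components$total)) {
        stop("train_protoseg: non-finite generator loss at iteration ", it,
             " (epoch ", epoch, "); last good checkpoint is epoch ",
             epoch - 1L)
      }
      ag_backward(tape, obj$total)
      grads <- lapply(pn, ag_grad)
      st <- sgd_step(gen, grads, v_gen, lr, cfg$momentum, cfg$clip)
      gen <- st$params; v_gen <- st$velocity
      # discriminator step (generator output detached)
      l_disc <- NA_real_
      if (use_disc) {
        tape2 <- ag_tape()
        pnd <- ag_leaves(tape2, disc)
        dobj <- discriminator_objective(tape2, pnd, ep, obj$pred, model,
                                        cfg$weights)
        l_disc <- ag_value(dobj)
        if (!is.finite(l_disc)) {
          stop("train_protoseg: non-finite discriminator loss at iteration ",
               it, "; last good checkpoint is epoch ", epoch - 1L)
        }
        ag_backward(tape2, dobj)
        gradd <- lapply(pnd, ag_grad)
        std <- sgd_step(disc, gradd, v_disc, lr, cfg$momentum, cfg$clip)
        disc <- std$params; v_disc <- std$velocity
      }
      cm <- obj$components
      acc["l_pro"] <- acc["l_pro"] + cm$l_pro
      if (!is.na(cm$l_align)) {
        acc["l_align"] <- acc["l_align"] + cm$l_align
        n_align <- n_align + 1L
      } else skips <- skips + 1L
      if (!is.na(cm$l_fpn)) acc["l_fpn"] <- acc["l_fpn"] + cm$l_fpn
      if (!is.na(cm$l_adv)) acc["l_adv"] <- acc["l_adv"] + cm$l_adv
      if (!is.na(l_disc)) acc["l_disc"] <- acc["l_disc"] + l_disc
      acc["total"] <- acc["total"] + cm$total
      acc["dsc"] <- acc["dsc"] + dsc(obj$pred, ep$query_mask)
      iter_log <- c(iter_log, cm$total)
    }
    n <- cfg$episodes_per_epoch
    metrics[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      l_pro = acc[["l_pro"]] / n,
      l_align = if (n_align > 0) acc[["l_align"]] / n_align else NA_real_,
      l_fpn = acc[["l_fpn"]] / n,
      l_adv = acc[["l_adv"]] / n,
      l_total = acc[["total"]] / n,
      l_disc = if (use_disc) acc[["l_disc"]] / n else NA_real_,
      train_dsc = acc[["dsc"]] / n,
      align_skips = skips)
    if (verbose) {
      m <- metrics[[epoch]]
      message(sprintf(
        "epoch %d  lr %.2e  L %.4f  pro %.4f  dsc %.1f  skips %d",
        epoch, lr, m$l_total, m$l_pro, m$train_dsc, m$align_skips))
    }
    if (!is.null(checkpoint_dir)) {
      if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, TRUE)
      saveRDS(list(gen = gen, disc = disc, epoch = epoch, cfg = cfg),
              file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
    }
  }
  model$params$gen <- gen
  model$params$disc <- disc
  model$metrics <- do.call(rbind, metrics)
  model$iter_log <- iter_log
  model$train_cfg <- cfg
  model
}

#' Segment a query slice from one support example
#'
#' Runs the full prototype pipeline: backbone features for support and query,
#' foreground/background local prototype sets from the support mask, scaled
#' cosine similarity stacks, prototype allocation, and the pixelwise
#' foreground/background argmax, upsampled (nearest) to image resolution.
#'
#' @param object a `protoseg_model`.
#' @param support_image,query_image numeric matrices.
#' @param support_mask binary matrix with at least one foreground pixel.
#' @param ... unused.
#' @return binary integer matrix of the query image's size.
#' @export
predict.protoseg_model <- function(object, support_image, support_mask,
                                   query_image, ...) {
  model <- object
  cfg <- model$backbone
  bb <- prefixed(model$params$gen, "bb.")
  Fs <- backbone_forward(support_image, cfg, params = bb)
  Fq <- backbone_forward(query_image, cfg, params = bb)
  dfac <- cfg$downsample_factor
  mf <- mask_to_feature(support_mask, dfac)
  if (sum(mf) <= 0) stop("predict: degenerate support mask")
  P_fg <- local_prototypes(Fs, mf, model$window_scale, model$tau, "fg")
  P_bg <- local_prototypes(Fs, 1 - mf, model$window_scale, model$tau, "bg")
  S_fg <- similarity_stack(Fq, P_fg, model$alpha_scale)
  S_bg <- similarity_stack(Fq, P_bg, model$alpha_scale)
  pm_fg <- allocate_probability(S_fg)
  pm_bg <- allocate_probability(S_bg)
  # score maps are upsampled bilinearly before the argmax so the predicted
  # boundary is not quantised to the feature-grid resolution
  final_prediction(upsample_bilinear(pm_fg, dfac),
                   upsample_bilinear(pm_bg, dfac))
}
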