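# Composite loss system: the prototype-branch cross-entropy, the reverse
# (alignment) regulariser, the multi-scale auxiliary loss, and the two
# adversarial terms linking generator and discriminator.

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Pixelwise two-class cross-entropy between probability maps and a label
#'
#' `mean(-[y log p_fg + (1-y) log p_bg])` over all pixels. Probabilities are
#' clamped at 1e-7 before the logarithm.
#'
#' @param p_fg,p_bg per-pixel foreground/background probabilities (normalised
#'   per pixel).
#' @param label binary matrix of the same shape.
#' @return non-negative scalar.
#' @export
#' @examples
#' ce_map_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2), matrix(1, 2, 2))  # ln 2
ce_map_loss <- function(p_fg, p_bg, label) {
  stopifnot(all(dim(p_fg) == dim(label)), all(dim(p_bg) == dim(label)))
  pf <- clamp_prob(p_fg); pb <- clamp_prob(p_bg)
  -mean(label * log(pf) + (1 - label) * log(pb))
}

# Nearest-neighbour downsample of a matrix to target size (integer factor).
label_at_scale <- function(label, h, w) {
  fy <- nrow(label) %/% h; fx <- ncol(label) %/% w
  label[seq.int(1L, by = fy, length.out = h),
        seq.int(1L, by = fx, length.out = w)]
}

#' Multi-scale auxiliary segmentation loss
#'
#' Sum over scales of the two-class cross-entropy between the softmaxed scale
#' logits and the label downsampled (nearest neighbour) to that scale.
#' Channel 1 is background, channel 2 foreground.
#'
#' @param scale_logits list of (h, w, 2) logit arrays (any order of scales).
#' @param label binary matrix at image resolution.
#' @return non-negative scalar.
#' @export
fpn_loss <- function(scale_logits, label) {
  stopifnot(length(scale_logits) >= 1L)
  total <- 0
  for (lg in scale_logits) {
    d <- dim(lg)
    y <- label_at_scale(label, d[1], d[2])
    p_fg <- stats::plogis(lg[, , 2] - lg[, , 1])
    total <- total + ce_map_loss(p_fg, 1 - p_fg, y)
  }
  total
}

#' Loss weights of the composite objective
#'
#' @param lambda0 adversarial weight in the generator objective (default 0.02).
#' @param lambda1 multi-scale auxiliary weight (default 0.3).
#' @param lambda2 discriminator query-term weight (default 0.5).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda0 = 0.02, lambda1 = 0.3, lambda2 = 0.5) {
  stopifnot(lambda0 >= 0, lambda1 >= 0, lambda2 >= 0)
  out <- list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2)
  class(out) <- "loss_weights"
  out
}

# Block-mean resampling of an image-resolution mask to the feature grid;
# returns soft occupancies in [0, 1].
mask_to_feature <- function(mask, factor) {
  H <- nrow(mask); W <- ncol(mask)
  h <- H %/% factor; w <- W %/% factor
  m <- mask
  dim(m) <- c(factor, h, factor * w)
  m <- colMeans(m)
  dim(m) <- c(h, factor, w)
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(factor, h * w)
  matrix(colMeans(m), h, w)
}

# Averaging matrix for the prototype pool of a given soft mask: local windows
# meeting the occupancy threshold, else the masked-global fallback column.
pool_matrix <- function(mask_f, window_scale, tau) {
  h <- nrow(mask_f); w <- ncol(mask_f)
  key <- paste("wp", h, w, window_scale, sep = "_")
  wp <- .proto_cache[[key]]
  if (is.null(wp)) {
    wp <- window_partition(h, w, window_scale)
    .proto_cache[[key]] <- wp
  }
  occ <- drop(crossprod(wp$A, c(mask_f)))
  keep <- which(occ >= tau)
  if (length(keep) > 0L) {
    list(A = wp$A[, keep, drop = FALSE], kind = "local", windows = keep)
  } else {
    s <- sum(mask_f)
    if (s <= 0) return(NULL)
    list(A = matrix(c(mask_f) / s, ncol = 1L), kind = "global",
         windows = NA_integer_)
  }
}

# Segmentation pass of the prototype branch on the tape. Fs/Fq are feature
# nodes; support_mask is a plain image-resolution mask. Returns nodes for the
# probability maps (feature and image resolution), soft foreground
# probability, hard prediction value, and the merged-feature ingredients.
proto_branch_tape <- function(tape, Fs, Fq, support_mask, model) {
  dfac <- model$backbone$downsample_factor
  mf <- mask_to_feature(support_mask, dfac)
  pm_fg <- pool_matrix(mf, model$window_scale, model$tau)
  pm_bg <- pool_matrix(1 - mf, model$window_scale, model$tau)
  if (is.null(pm_fg) || is.null(pm_bg)) return(NULL)
  P_fg <- ag_pool_mat(tape, Fs, pm_fg$A)
  P_bg <- ag_pool_mat(tape, Fs, pm_bg$A)
  D_fg <- ag_cosine(tape, Fq, P_fg, model$alpha_scale)
  D_bg <- ag_cosine(tape, Fq, P_bg, model$alpha_scale)
  PM_fg <- ag_alloc(tape, D_fg)
  PM_bg <- ag_alloc(tape, D_bg)
  up <- function(x) {
    d <- dim(ag_value(x))
    x3 <- ag_reshape(tape, x, c(d[1], d[2], 1L))
    u <- ag_upsample(tape, x3, dfac)
    du <- dim(ag_value(u))
    ag_reshape(tape, u, du[1:2])
  }
  PM_fg_img <- up(PM_fg)
  PM_bg_img <- up(PM_bg)
  z <- ag_sub(tape, PM_fg_img, PM_bg_img)
  p_fg <- ag_sigmoid(tape, z)
  pred <- (ag_value(PM_fg_img) > ag_value(PM_bg_img)) * 1
  list(P_fg = P_fg, P_bg = P_bg, D_fg = D_fg, D_bg = D_bg,
       PM_fg = PM_fg, PM_bg = PM_bg,
       PM_fg_img = PM_fg_img, PM_bg_img = PM_bg_img,
       p_fg = p_fg, pred = pred)
}

# Full generator objective on a fresh tape. Returns the total-loss node plus
# component values; disc_params enter as constants so no gradient reaches the
# discriminator.
generator_objective <- function(tape, pn_gen, episode, model, w,
                                disc_params = NULL) {
  cfg <- model$backbone
  Fs <- backbone_forward_tape(tape, prefixed(pn_gen, "bb."),
                              episode$support_image, cfg)
  Fq <- backbone_forward_tape(tape, prefixed(pn_gen, "bb."),
                              episode$query_image, cfg)
  fwd <- proto_branch_tape(tape, Fs, Fq, episode$support_mask, model)
  if (is.null(fwd)) stop("generator_objective: degenerate support mask")
  l_pro <- ag_softmax_ce(tape, fwd$PM_fg_img, fwd$PM_bg_img,
                         episode$query_mask)
  parts <- list(l_pro)
  weights <- 1
  # prototypical alignment regularisation: roles swapped
  align_skipped <- TRUE
  l_align_val <- NA_real_
  if (!anyNA(fwd$pred) && sum(fwd$pred) > 0) {
    back <- proto_branch_tape(tape, Fq, Fs, fwd$pred, model)
    if (!is.null(back)) {
      l_align <- ag_softmax_ce(tape, back$PM_fg_img, back$PM_bg_img,
                               episode$support_mask)
      parts <- c(parts, list(l_align))
      weights <- c(weights, 1)
      align_skipped <- FALSE
      l_align_val <- ag_value(l_align)
    }
  }
  # multi-scale auxiliary branch
  l_fpn_val <- NA_real_
  if (!is.null(model$fpn)) {
    D_all <- array(c(ag_value(fwd$D_fg), ag_value(fwd$D_bg)),
                   dim = dim(ag_value(fwd$D_fg)) + c(0, 0, dim(ag_value(fwd$D_bg))[3]))
    P_all <- ag_rbind2(tape, fwd$P_fg, fwd$P_bg)
    FG <- ag_guide(tape, ag_leaf(tape, D_all), P_all)
    d <- dim(ag_value(fwd$PM_fg))
    Fm <- ag_concat_c(tape, list(
      FG, ag_reshape(tape, fwd$PM_fg, c(d[1], d[2], 1L)), Fq))
    logits <- fpn_forward_tape(tape, prefixed(pn_gen, "fpn."), Fm, model$fpn)
    ls <- lapply(logits, function(lg) {
      dl <- dim(ag_value(lg))
      y <- label_at_scale(episode$query_mask, dl[1], dl[2])
      ag_softmax_ce(tape, ag_channel(tape, lg, 2L), ag_channel(tape, lg, 1L), y)
    })
    l_fpn <- ag_axpy(tape, ls)
    parts <- c(parts, list(l_fpn))
    weights <- c(weights, w$lambda1)
    l_fpn_val <- ag_value(l_fpn)
  }
  # adversarial term: discriminator scores the generator's hard mask
  # (straight-through: gradient reaches the soft foreground probability)
  l_adv_val <- NA_real_
  if (!is.null(disc_params) && w$lambda0 > 0) {
    d <- dim(ag_value(fwd$p_fg))
    hard <- ag_hard_st(tape, fwd$p_fg)
    mask3 <- ag_reshape(tape, hard, c(d[1], d[2], 1L))
    z <- gnet_logit_tape(tape, disc_params, episode$query_image,
                         mask3, model$gnet)
    l_adv <- ag_bce_logit(tape, z, 1)
    parts <- c(parts, list(l_adv))
    weights <- c(weights, w$lambda0)
    l_adv_val <- ag_value(l_adv)
  }
  total <- ag_axpy(tape, parts, weights)
  list(total = total,
       components = list(
         l_pro = ag_value(l_pro),
         l_align = l_align_val,
         l_fpn = l_fpn_val,
         l_adv = l_adv_val,
         total = ag_value(total)),
       pred = fwd$pred, align_skipped = align_skipped)
}

prefixed <- function(pn, prefix) {
  sel <- startsWith(names(pn), prefix)
  out <- pn[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

# Discriminator objective: support pair scored toward 1, the generator's
# (detached) query prediction toward 0, weighted by lambda2.
discriminator_objective <- function(tape, pn_disc, episode, pred_mask,
                                    model, w) {
  d <- c(dim(episode$support_mask), 1L)
  zs <- gnet_logit_tape(tape, pn_disc, episode$support_image,
                        array(episode$support_mask, d), model$gnet)
  zq <- gnet_logit_tape(tape, pn_disc, episode$query_image,
                        array(pred_mask, d), model$gnet)
  ls <- ag_bce_logit(tape, zs, 1)
  lq <- ag_bce_logit(tape, zq, 0)
  ag_axpy(tape, list(ls, lq), c(1, w$lambda2))
}

#' Generator loss on one episode
#'
#' Composite objective of the segmentation network: the prototype-branch
#' cross-entropy, the alignment regulariser (roles of support and query
#' swapped, using the predicted query mask as pseudo-support), the
#' multi-scale auxiliary loss weighted by `lambda1`, and the adversarial
#' reward weighted by `lambda0` (the generator is rewarded when the
#' discriminator scores its query mask as support-like). The alignment term
#' is skipped (reported as NA) when the predicted mask is empty.
#'
#' @param episode a `protoseg_episode`.
#' @param model a [protoseg_model()].
#' @param w a [loss_weights()].
#' @return list with `total` and per-component values (`l_pro`, `l_align`,
#'   `l_fpn`, `l_adv`).
#' @export
generator_loss <- function(episode, model, w = loss_weights()) {
  tape <- ag_tape()
  pn <- ag_leaves(tape, model$params$gen)
  obj <- generator_objective(tape, pn, episode, model, w,
                             disc_params = model$params$disc)
  obj$components
}

#' Discriminator loss on one episode
#'
#' `L_G = BCE(score(support image, support mask), 1) +
#' lambda2 * BCE(score(query image, predicted query mask), 0)`; the predicted
#' mask is detached from the generator.
#'
#' @inheritParams generator_loss
#' @return scalar loss value.
#' @export
discriminator_loss <- function(episode, model, w = loss_weights()) {
  if (is.null(model$params$disc)) stop("model has no discriminator")
  pred <- predict(model, episode$support_image, episode$support_mask,
                  episode$query_image)
  tape <- ag_tape()
  pn <- ag_leaves(tape, model$params$disc)
  ag_value(discriminator_objective(tape, pn, episode, pred, model, w))
}

#' Alignment (reverse-direction) loss on one episode
#'
#' The query image and its predicted mask act as the new support; the
#' original support image is segmented and scored by cross-entropy against
#' the original support mask. Returns `NA` when the predicted query mask is
#' empty (the term is skipped during training and counted).
#'
#' @inheritParams generator_loss
#' @return scalar loss value, or `NA` if skipped.
#' @export
alignment_loss <- function(episode, model) {
  tape <- ag_tape()
  pn <- ag_leaves(tape, model$params$gen)
  obj <- generator_objective(tape, pn, episode, model,
                             loss_weights(lambda0 = 0, lambda1 = 0),
                             disc_params = NULL)
  obj$components$l_align
}
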