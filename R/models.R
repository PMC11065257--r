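# Learnable components: feature-extractor backbones, the FPN-like multi-scale
# prediction head, and the mask-quality discriminator with dual-attentive
# fusion. Parameters are flat named lists of arrays; forward passes run on the
# autograd tape (or with a NULL tape for plain inference values).

# He-style weights, zero biases. A consequence worth noting: with all-zero
# biases a ReLU network is positively homogeneous, so at initialisation
# constant image regions of different intensity yield (near) parallel
# feature vectors and the cosine metric can barely separate them - the
# untrained model is close to intensity-blind, and breaking this symmetry
# is precisely what episodic training has to learn.
he_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}
bias_init <- function(n, fan_in) numeric(n)
he_dense <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}

#' Backbone configuration
#'
#' @param family `"tiny_cnn"` (a three-conv net for desk-scale runs, one input
#'   channel) or `"resnet"` (a configurable residual bottleneck backbone; the
#'   full-scale 101-layer variant used on real data is one configuration of
#'   this family, but no pretrained weights are bundled).
#' @param out_channels feature channels emitted (>= 8).
#' @param downsample_factor spatial reduction, 4 or 8.
#' @param width internal channel width (defaults to `out_channels`).
#' @param depths for `"resnet"`: bottleneck blocks per stage.
#' @param pretrained accepted for interface compatibility; must be FALSE
#'   (no weights ship with the package).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(family = c("tiny_cnn", "resnet"),
                            out_channels = 16L, downsample_factor = 4L,
                            width = out_channels, depths = c(1L, 1L),
                            pretrained = FALSE) {
  family <- match.arg(family)
  stopifnot(out_channels >= 8L, downsample_factor %in% c(4L, 8L))
  if (isTRUE(pretrained)) stop("backbone_config: no pretrained weights available")
  out <- list(family = family, out_channels = as.integer(out_channels),
              downsample_factor = as.integer(downsample_factor),
              width = as.integer(width), depths = as.integer(depths))
  class(out) <- "backbone_config"
  out
}

init_backbone <- function(cfg) {
  w <- cfg$width; oc <- cfg$out_channels
  p <- list()
  if (cfg$family == "tiny_cnn") {
    p[["c1.W"]] <- he_conv(3, 3, 1, w);  p[["c1.b"]] <- bias_init(w, 9)
    p[["c2.W"]] <- he_conv(3, 3, w, w);  p[["c2.b"]] <- bias_init(w, 9 * w)
    p[["c3.W"]] <- he_conv(3, 3, w, oc); p[["c3.b"]] <- bias_init(oc, 9 * w)
    if (cfg$downsample_factor == 8L) {
      p[["c4.W"]] <- he_conv(3, 3, oc, oc); p[["c4.b"]] <- bias_init(oc, 9 * oc)
    }
  } else {
    b <- max(4L, w %/% 2L)
    p[["stem.W"]] <- he_conv(3, 3, 1, w); p[["stem.b"]] <- bias_init(w, 9)
    n_stages <- if (cfg$downsample_factor == 4L) 2L else 3L
    for (s in seq_len(n_stages)) {
      nb <- cfg$depths[min(s, length(cfg$depths))]
      for (j in seq_len(nb)) {
        pre <- sprintf("s%d.b%d", s, j)
        p[[paste0(pre, ".r.W")]] <- he_conv(1, 1, w, b)
        p[[paste0(pre, ".r.b")]] <- bias_init(b, w)
        p[[paste0(pre, ".m.W")]] <- he_conv(3, 3, b, b)
        p[[paste0(pre, ".m.b")]] <- bias_init(b, 9 * b)
        p[[paste0(pre, ".e.W")]] <- he_conv(1, 1, b, w)
        p[[paste0(pre, ".e.b")]] <- bias_init(w, b)
      }
    }
    p[["proj.W"]] <- he_conv(1, 1, w, oc); p[["proj.b"]] <- bias_init(oc, w)
  }
  p
}

backbone_forward_tape <- function(tape, pn, image, cfg) {
  x <- ag_as_image3d(tape, image)
  if (cfg$family == "tiny_cnn") {
    x <- ag_relu(tape, ag_conv2d(tape, x, pn[["c1.W"]], pn[["c1.b"]]))
    x <- ag_avgpool(tape, x, 2L)
    x <- ag_relu(tape, ag_conv2d(tape, x, pn[["c2.W"]], pn[["c2.b"]]))
    x <- ag_avgpool(tape, x, 2L)
    x <- ag_relu(tape, ag_conv2d(tape, x, pn[["c3.W"]], pn[["c3.b"]]))
    if (cfg$downsample_factor == 8L) {
      x <- ag_avgpool(tape, x, 2L)
      x <- ag_relu(tape, ag_conv2d(tape, x, pn[["c4.W"]], pn[["c4.b"]]))
    }
  } else {
    x <- ag_relu(tape, ag_conv2d(tape, x, pn[["stem.W"]], pn[["stem.b"]]))
    n_stages <- if (cfg$downsample_factor == 4L) 2L else 3L
    for (s in seq_len(n_stages)) {
      x <- ag_avgpool(tape, x, 2L)
      nb <- cfg$depths[min(s, length(cfg$depths))]
      for (j in seq_len(nb)) {
        pre <- sprintf("s%d.b%d", s, j)
        h <- ag_relu(tape, ag_conv2d(tape, x, pn[[paste0(pre, ".r.W")]],
                                     pn[[paste0(pre, ".r.b")]], pad = 0L))
        h <- ag_relu(tape, ag_conv2d(tape, h, pn[[paste0(pre, ".m.W")]],
                                     pn[[paste0(pre, ".m.b")]]))
        h <- ag_conv2d(tape, h, pn[[paste0(pre, ".e.W")]],
                       pn[[paste0(pre, ".e.b")]], pad = 0L)
        x <- ag_relu(tape, ag_add(tape, x, h))
      }
    }
    x <- ag_relu(tape, ag_conv2d(tape, x, pn[["proj.W"]], pn[["proj.b"]],
                                 pad = 0L))
  }
  x
}

#' Run a backbone over one slice
#'
#' @param image numeric matrix whose spatial size is divisible by the
#'   configured downsample factor.
#' @param cfg a [backbone_config()].
#' @param params parameter list from model initialisation; when omitted,
#'   fresh seeded parameters are drawn (useful for shape checks).
#' @param seed seed for fresh parameters.
#' @return feature array, dim c(H/d, W/d, out_channels).
#' @export
backbone_forward <- function(image, cfg = backbone_config(), params = NULL,
                             seed = 1L) {
  d <- cfg$downsample_factor
  if (nrow(image) %% d != 0L || ncol(image) %% d != 0L) {
    stop("backbone_forward: spatial size must be a multiple of ", d)
  }
  if (is.null(params)) params <- withr::with_seed(seed, init_backbone(cfg))
  tape <- ag_tape()
  pn <- ag_leaves(tape, params)
  ag_value(backbone_forward_tape(tape, pn, image, cfg))
}

#' FPN-like multi-scale head configuration
#'
#' @param n_scales number of prediction scales (coarse to fine).
#' @param lateral_channels channels of the lateral/top-down pathway.
#' @param in_channels channels of the merged feature input.
#' @return object of class `fpn_config`.
#' @export
fpn_config <- function(n_scales = 3L, lateral_channels = 16L,
                       in_channels = 33L) {
  out <- list(n_scales = as.integer(n_scales),
              lateral_channels = as.integer(lateral_channels),
              in_channels = as.integer(in_channels))
  class(out) <- "fpn_config"
  out
}

init_fpn <- function(cfg) {
  L <- cfg$lateral_channels
  p <- list()
  p[["entry.W"]] <- he_conv(3, 3, cfg$in_channels, L)
  p[["entry.b"]] <- bias_init(L, 9 * cfg$in_channels)
  for (l in seq_len(cfg$n_scales)) {
    p[[sprintf("lat%d.W", l)]] <- he_conv(1, 1, L, L)
    p[[sprintf("lat%d.b", l)]] <- bias_init(L, L)
    p[[sprintf("pred%d.W", l)]] <- he_conv(1, 1, L, 2)
    p[[sprintf("pred%d.b", l)]] <- bias_init(2, L)
  }
  p
}

# Returns list of 2-channel logit nodes ordered coarse -> fine.
fpn_forward_tape <- function(tape, pn, Fm, cfg) {
  ns <- cfg$n_scales
  x <- ag_relu(tape, ag_conv2d(tape, Fm, pn[["entry.W"]], pn[["entry.b"]]))
  xs <- vector("list", ns)            # fine (1) -> coarse (ns)
  xs[[1]] <- x
  for (l in seq_len(ns - 1L)) xs[[l + 1L]] <- ag_avgpool(tape, xs[[l]], 2L)
  td <- vector("list", ns)
  for (l in seq.int(ns, 1L)) {        # top-down pathway
    lat <- ag_conv2d(tape, xs[[l]], pn[[sprintf("lat%d.W", l)]],
                     pn[[sprintf("lat%d.b", l)]], pad = 0L)
    td[[l]] <- if (l == ns) lat else
      ag_add(tape, lat, ag_upsample(tape, td[[l + 1L]], 2L))
  }
  # emit coarse -> fine
  lapply(seq.int(ns, 1L), function(l) {
    ag_conv2d(tape, td[[l]], pn[[sprintf("pred%d.W", l)]],
              pn[[sprintf("pred%d.b", l)]], pad = 0L)
  })
}

#' Run the multi-scale prediction head over a merged feature grid
#'
#' @param F_m merged feature array (H, W, in_channels).
#' @param cfg an [fpn_config()]; `in_channels` must match `F_m`.
#' @param params parameter list; fresh seeded parameters when omitted.
#' @param seed seed for fresh parameters.
#' @return list of 2-channel logit arrays ordered coarse to fine; scale `l`
#'   (1 = coarsest) has spatial size `(H, W) / 2^(n_scales - l)`.
#' @export
fpn_forward <- function(F_m, cfg = fpn_config(in_channels = dim(F_m)[3]),
                        params = NULL, seed = 1L) {
  stopifnot(dim(F_m)[3] == cfg$in_channels)
  if (is.null(params)) params <- withr::with_seed(seed, init_fpn(cfg))
  tape <- ag_tape()
  pn <- ag_leaves(tape, params)
  x <- ag_leaf(tape, F_m)
  lapply(fpn_forward_tape(tape, pn, x, cfg), ag_value)
}

#' Discriminator configuration
#'
#' @param n_dense_blocks total dense blocks (one before the attention stage,
#'   the rest after fusion).
#' @param growth channels added by each dense-block layer.
#' @param n_layers layers per dense block.
#' @param single_path if TRUE only the foreground attention path is used
#'   (ablation variant); default FALSE (dual-attentive fusion).
#' @param head_hidden hidden widths of the three-layer score head.
#' @return object of class `discriminator_config`.
#' @export
discriminator_config <- function(n_dense_blocks = 3L, growth = 16L,
                                 n_layers = 2L, single_path = FALSE,
                                 head_hidden = c(32L, 16L)) {
  out <- list(n_dense_blocks = as.integer(n_dense_blocks),
              growth = as.integer(growth), n_layers = as.integer(n_layers),
              single_path = isTRUE(single_path),
              head_hidden = as.integer(head_hidden))
  class(out) <- "discriminator_config"
  out
}

dense_block_channels <- function(cin, cfg) cin + cfg$n_layers * cfg$growth

init_dense_block <- function(prefix, cin, cfg) {
  p <- list()
  ch <- cin
  for (l in seq_len(cfg$n_layers)) {
    p[[sprintf("%s.l%d.W", prefix, l)]] <- he_conv(3, 3, ch, cfg$growth)
    p[[sprintf("%s.l%d.b", prefix, l)]] <- bias_init(cfg$growth, 9 * ch)
    ch <- ch + cfg$growth
  }
  p
}

dense_block_tape <- function(tape, pn, prefix, x, cfg) {
  for (l in seq_len(cfg$n_layers)) {
    h <- ag_relu(tape, ag_conv2d(tape, x, pn[[sprintf("%s.l%d.W", prefix, l)]],
                                 pn[[sprintf("%s.l%d.b", prefix, l)]]))
    x <- ag_concat_c(tape, list(x, h))
  }
  x
}

init_discriminator <- function(cfg) {
  g <- cfg$growth
  c1 <- dense_block_channels(1L, cfg)
  p <- init_dense_block("db1", 1L, cfg)
  for (path in c("fg", "bg")) {
    p[[sprintf("att_%s.mask.W", path)]] <- he_conv(3, 3, 1, c1)
    p[[sprintf("att_%s.mask.b", path)]] <- bias_init(c1, 9)
    p[[sprintf("att_%s.refine.W", path)]] <- he_conv(3, 3, c1, c1)
    p[[sprintf("att_%s.refine.b", path)]] <- bias_init(c1, 9 * c1)
  }
  ch <- if (cfg$single_path) c1 else 2L * c1
  for (bidx in seq_len(cfg$n_dense_blocks - 1L)) {
    p <- c(p, init_dense_block(sprintf("db%d", bidx + 1L), ch, cfg))
    ch <- dense_block_channels(ch, cfg)
  }
  h <- cfg$head_hidden
  p[["head1.W"]] <- he_dense(ch, h[1]); p[["head1.b"]] <- bias_init(h[1], ch)
  p[["head2.W"]] <- he_dense(h[1], h[2]); p[["head2.b"]] <- bias_init(h[2], h[1])
  # final score-head bias starts at zero so an untrained head scores 0.5
  p[["head3.W"]] <- he_dense(h[2], 1L); p[["head3.b"]] <- numeric(1L)
  p
}

attention_fuse_tape <- function(tape, pn, prefix, feat, mask) {
  a <- ag_sigmoid(tape, ag_conv2d(tape, mask,
                                  pn[[sprintf("%s.mask.W", prefix)]],
                                  pn[[sprintf("%s.mask.b", prefix)]]))
  m <- ag_mul(tape, feat, a)
  r <- ag_conv2d(tape, m, pn[[sprintf("%s.refine.W", prefix)]],
                 pn[[sprintf("%s.refine.b", prefix)]])
  ag_add(tape, r, feat)
}

#' Attentive fusion of image features with a mask
#'
#' The mask passes through a convolution and a sigmoid to give per-channel
#' attention, which multiplies the image features elementwise; the attended
#' features are refined by a second convolution and added back to the input
#' features (residual path). The mask is resampled to the feature resolution
#' by nearest neighbour when the sizes differ.
#'
#' @param image_features feature array (H, W, C).
#' @param mask binary matrix; any resolution whose size is an integer
#'   multiple of the feature size.
#' @param params list with `mask.W` (3x3x1xC), `mask.b`, `refine.W`
#'   (3x3xCxC), `refine.b`.
#' @return feature array with the same shape as `image_features`.
#' @export
attention_fuse <- function(image_features, mask, params) {
  d <- dim(image_features)
  f <- nrow(mask) %/% d[1]
  m <- if (f > 1L) mask[seq.int(1L, nrow(mask), by = f),
                        seq.int(1L, ncol(mask), by = f)] else mask
  tape <- ag_tape()
  pn <- list(att.mask.W = ag_leaf(tape, params[["mask.W"]]),
             att.mask.b = ag_leaf(tape, params[["mask.b"]]),
             att.refine.W = ag_leaf(tape, params[["refine.W"]]),
             att.refine.b = ag_leaf(tape, params[["refine.b"]]))
  feat <- ag_leaf(tape, image_features)
  mnode <- ag_leaf(tape, array(m, c(d[1], d[2], 1L)))
  ag_value(attention_fuse_tape(tape, pn, "att", feat, mnode))
}

# Full discriminator forward; image (H,W) node/array, mask (H,W,1) node/array
# at image resolution. Returns the score logit node.
gnet_logit_tape <- function(tape, pn, image, mask, cfg) {
  x <- ag_as_image3d(tape, image)
  x <- ag_avgpool(tape, x, 2L)             # work at half resolution
  feat <- dense_block_tape(tape, pn, "db1", x, cfg)
  m <- if (is_ag_node(mask)) ag_subsample(tape, mask, 2L) else {
    v <- mask
    v[seq.int(1L, dim(v)[1], 2L), seq.int(1L, dim(v)[2], 2L), , drop = FALSE]
  }
  minv <- ag_sub(tape, array(1, dim(ag_value(m))), m)
  afg <- attention_fuse_tape(tape, pn, "att_fg", feat, m)
  if (cfg$single_path) {
    fused <- afg
  } else {
    abg <- attention_fuse_tape(tape, pn, "att_bg", feat, minv)
    fused <- ag_concat_c(tape, list(afg, abg))
  }
  x <- fused
  for (bidx in seq_len(cfg$n_dense_blocks - 1L)) {
    x <- ag_avgpool(tape, x, 2L)
    x <- dense_block_tape(tape, pn, sprintf("db%d", bidx + 1L), x, cfg)
  }
  v <- ag_gap(tape, x)
  v <- ag_relu(tape, ag_dense(tape, v, pn[["head1.W"]], pn[["head1.b"]]))
  v <- ag_relu(tape, ag_dense(tape, v, pn[["head2.W"]], pn[["head2.b"]]))
  ag_dense(tape, v, pn[["head3.W"]], pn[["head3.b"]])
}

#' Score a (image, mask) pair with the discriminator
#'
#' The discriminator sees the image, the mask and its inverse; the two
#' attentive feature maps are concatenated (dual-attentive fusion), passed
#' through further dense blocks and a three-layer classifier head ending in a
#' sigmoid. A score near 1 means the mask looks like a faithful, support-like
#' annotation of the image; near 0 means poor quality.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param cfg a [discriminator_config()].
#' @param params parameter list; fresh seeded parameters when omitted.
#' @param seed seed for fresh parameters.
#' @return scalar strictly inside (0, 1).
#' @export
gnet_score <- function(image, mask, cfg = discriminator_config(),
                       params = NULL, seed = 1L) {
  stopifnot(all(dim(image) == dim(mask)))
  if (!all(mask %in% c(0, 1))) stop("gnet_score: mask must be binary")
  if (is.null(params)) params <- withr::with_seed(seed, init_discriminator(cfg))
  tape <- ag_tape()
  pn <- ag_leaves(tape, params)
  mnode <- ag_leaf(tape, array(mask, c(nrow(mask), ncol(mask), 1L)))
  z <- gnet_logit_tape(tape, pn, image, mnode, cfg)
  stats::plogis(ag_value(z))
}

#' Initialise a full few-shot segmentation model
#'
#' Bundles the backbone, the prototype-branch hyperparameters, the optional
#' multi-scale head and the optional discriminator into one model object with
#' seeded He-initialised weights (zero biases).
#'
#' @param backbone a [backbone_config()].
#' @param fpn an [fpn_config()] or `NULL` to disable the multi-scale head.
#' @param gnet a [discriminator_config()] or `NULL` to disable the
#'   discriminator.
#' @param window_scale local prototype pooling window scale (fraction).
#' @param tau occupancy threshold for local prototypes.
#' @param alpha_scale cosine similarity multiplier.
#' @param seed integer seed for weight initialisation.
#' @return object of class `protoseg_model`.
#' @export
protoseg_model <- function(backbone = backbone_config(),
                           fpn = fpn_config(in_channels = 2L * backbone$out_channels + 1L),
                           gnet = discriminator_config(),
                           window_scale = 0.25, tau = 0.95, alpha_scale = 20,
                           seed = 1L) {
  params <- withr::with_seed(seed, {
    bb <- init_backbone(backbone)
    names(bb) <- paste0("bb.", names(bb))
    gen <- bb
    if (!is.null(fpn)) {
      fp <- init_fpn(fpn)
      names(fp) <- paste0("fpn.", names(fp))
      gen <- c(gen, fp)
    }
    disc <- if (!is.null(gnet)) init_discriminator(gnet) else NULL
    list(gen = gen, disc = disc)
  })
  out <- list(backbone = backbone, fpn = fpn, gnet = gnet,
              window_scale = window_scale, tau = tau,
              alpha_scale = alpha_scale, seed = as.integer(seed),
              params = params, train_classes = NULL, metrics = NULL)
  class(out) <- "protoseg_model"
  out
}

#' @export
print.protoseg_model <- function(x, ...) {
  np <- sum(vapply(x$params$gen, length, numeric(1)))
  nd <- if (!is.null(x$params$disc)) {
    sum(vapply(x$params$disc, length, numeric(1)))
  } else 0
  cat("<protoseg_model>", x$backbone$family, "backbone,",
      np, "generator +", nd, "discriminator weights;",
      if (is.null(x$fpn)) "no multi-scale head;" else "multi-scale head;",
      if (is.null(x$gnet)) "no discriminator\n" else "adversarial discriminator\n")
  if (!is.null(x$train_classes)) {
    cat("  trained on classes:", paste(x$train_classes, collapse = ", "), "\n")
  }
  invisible(x)
}
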