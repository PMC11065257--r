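# Learnable components: shapes, determinism, forced-weight behaviours.

test_that("backbone output shape follows the downsample factor", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  F4 <- backbone_forward(img, backbone_config("tiny_cnn", out_channels = 8L))
  expect_equal(dim(F4), c(16, 16, 8))
  F8 <- backbone_forward(img, backbone_config("tiny_cnn", out_channels = 8L,
                                              downsample_factor = 8L))
  expect_equal(dim(F8), c(8, 8, 8))
  expect_error(
    backbone_forward(matrix(0, 30, 30), backbone_config("tiny_cnn")),
    "multiple")
})

test_that("backbone forward is deterministic and finite", {
  img <- matrix(stats::runif(32 * 32), 32, 32)
  cfg <- backbone_config("tiny_cnn", out_channels = 8L)
  p <- withr::with_seed(2, protoseg:::init_backbone(cfg))
  expect_identical(backbone_forward(img, cfg, params = p),
                   backbone_forward(img, cfg, params = p))
  expect_true(all(is.finite(backbone_forward(img, cfg, params = p))))
})

test_that("swapping backbone families changes only the channel count", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  Ft <- backbone_forward(img, backbone_config("tiny_cnn", out_channels = 8L))
  Fr <- backbone_forward(img, backbone_config("resnet", out_channels = 12L,
                                              width = 8L))
  expect_equal(dim(Ft)[1:2], dim(Fr)[1:2])
  expect_equal(dim(Fr)[3], 12)
  expect_true(all(is.finite(Fr)))
})

test_that("multi-scale head emits a dyadic pyramid of 2-channel maps", {
  Fm <- array(stats::rnorm(32 * 32 * 17), c(32, 32, 17))
  cfg <- fpn_config(n_scales = 3L, lateral_channels = 8L, in_channels = 17L)
  logits <- fpn_forward(Fm, cfg)
  expect_length(logits, 3)
  expect_equal(dim(logits[[1]]), c(8, 8, 2))     # coarse first
  expect_equal(dim(logits[[2]]), c(16, 16, 2))
  expect_equal(dim(logits[[3]]), c(32, 32, 2))
})

test_that("a zero-weight head yields zero logits hence uniform predictions", {
  cfg <- fpn_config(n_scales = 2L, lateral_channels = 4L, in_channels = 5L)
  p <- withr::with_seed(1, protoseg:::init_fpn(cfg))
  p <- lapply(p, function(w) w * 0)
  Fm <- array(stats::rnorm(16 * 16 * 5), c(16, 16, 5))
  logits <- fpn_forward(Fm, cfg, params = p)
  for (lg in logits) {
    expect_true(all(lg == 0))
    prob <- stats::plogis(lg[, , 2] - lg[, , 1])
    expect_true(all(prob == 0.5))
  }
})

test_that("a single-scale head equals one convolutional classifier", {
  cfg <- fpn_config(n_scales = 1L, lateral_channels = 6L, in_channels = 9L)
  p <- withr::with_seed(3, protoseg:::init_fpn(cfg))
  Fm <- array(stats::rnorm(12 * 12 * 9), c(12, 12, 9))
  got <- fpn_forward(Fm, cfg, params = p)[[1]]
  # oracle: entry conv + relu, lateral 1x1, prediction 1x1, composed directly
  tape <- protoseg:::ag_tape()
  h <- protoseg:::ag_relu(tape, protoseg:::ag_conv2d(
    tape, Fm, p[["entry.W"]], p[["entry.b"]]))
  h <- protoseg:::ag_conv2d(tape, h, p[["lat1.W"]], p[["lat1.b"]], pad = 0L)
  h <- protoseg:::ag_conv2d(tape, h, p[["pred1.W"]], p[["pred1.b"]], pad = 0L)
  expect_equal(got, protoseg:::ag_value(h), tolerance = 1e-12)
})

test_that("attention fusion honours forced weights", {
  C <- 5L
  feat <- array(stats::rnorm(16 * 16 * C), c(16, 16, C))
  mask <- matrix(rbinom(256, 1, 0.3), 16, 16)
  # sigmoid ~ 1 everywhere, refine = identity (centre tap) => out = 2 * feat
  pid <- array(0, c(3, 3, C, C))
  for (ch in seq_len(C)) pid[2, 2, ch, ch] <- 1
  params <- list(mask.W = array(0, c(3, 3, 1, C)), mask.b = rep(30, C),
                 refine.W = pid, refine.b = numeric(C))
  out <- attention_fuse(feat, mask, params)
  expect_equal(out, 2 * feat, tolerance = 1e-10)
  # refine forced to zero: residual path only
  params$refine.W <- array(0, c(3, 3, C, C))
  expect_identical(attention_fuse(feat, mask, params), feat)
  # shape contract holds when the mask is higher resolution
  big_mask <- matrix(rbinom(1024, 1, 0.3), 32, 32)
  expect_equal(dim(attention_fuse(feat, big_mask, params)), dim(feat))
})

test_that("discriminator scores sit strictly inside (0,1) and depend on mask
           orientation", {
  img <- matrix(stats::runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[8:20, 10:22] <- 1
  cfg <- discriminator_config(growth = 4L, head_hidden = c(8L, 4L))
  p <- withr::with_seed(6, protoseg:::init_discriminator(cfg))
  s1 <- gnet_score(img, msk, cfg, params = p)
  s2 <- gnet_score(img, 1 - msk, cfg, params = p)
  expect_gt(s1, 0); expect_lt(s1, 1)
  expect_false(isTRUE(all.equal(s1, s2)))  # paths are not weight-tied
  expect_error(gnet_score(img, msk * 0.5, cfg, params = p), "binary")
})

test_that("a zero score head gives exactly 0.5", {
  img <- matrix(stats::runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[4:10, 4:10] <- 1
  cfg <- discriminator_config(growth = 4L, head_hidden = c(8L, 4L))
  p <- withr::with_seed(7, protoseg:::init_discriminator(cfg))
  p[["head3.W"]] <- p[["head3.W"]] * 0
  p[["head3.b"]] <- 0
  expect_equal(gnet_score(img, msk, cfg, params = p), 0.5)
})

test_that("the single-path ablation uses only the foreground attention", {
  img <- matrix(stats::runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[8:16, 8:16] <- 1
  cfg1 <- discriminator_config(growth = 4L, head_hidden = c(8L, 4L),
                               single_path = TRUE)
  p1 <- withr::with_seed(8, protoseg:::init_discriminator(cfg1))
  s <- gnet_score(img, msk, cfg1, params = p1)
  expect_gt(s, 0); expect_lt(s, 1)
  # background attention weights never influence the single-path score
  p1b <- p1
  p1b[["att_bg.mask.W"]] <- p1b[["att_bg.mask.W"]] + 1
  expect_identical(gnet_score(img, msk, cfg1, params = p1b), s)
})

test_that("model constructor wires components and prints", {
  m <- tiny_test_model(seed = 2)
  expect_s3_class(m, "protoseg_model")
  expect_true(any(startsWith(names(m$params$gen), "bb.")))
  expect_true(any(startsWith(names(m$params$gen), "fpn.")))
  expect_false(is.null(m$params$disc))
  expect_output(print(m), "backbone")
  m2 <- tiny_test_model(seed = 2)
  expect_identical(m$params, m2$params)   # seeded init
})
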