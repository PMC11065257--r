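# Finite-difference validation of the reverse-mode tape, op by op and
# through the smooth part of the episodic objective.

grad_check <- function(build, params, n_probe = 3, tol = 1e-4) {
  f <- function(p) {
    tape <- protoseg:::ag_tape()
    pn <- protoseg:::ag_leaves(tape, p)
    protoseg:::ag_value(build(tape, pn))
  }
  tape <- protoseg:::ag_tape()
  pn <- protoseg:::ag_leaves(tape, params)
  out <- build(tape, pn)
  protoseg:::ag_backward(tape, out)
  for (nm in names(params)) {
    g <- protoseg:::ag_grad(pn[[nm]])
    expect_false(is.null(g), label = paste("gradient exists for", nm))
    idx <- sample(length(params[[nm]]), min(n_probe, length(params[[nm]])))
    for (i in idx) {
      fd <- fd_grad(f, params, nm, i)
      expect_equal(g[i], fd, tolerance = tol,
                   label = paste0("d/d", nm, "[", i, "]"))
    }
  }
}

test_that("convolution, pooling and dense gradients match finite differences", {
  withr::with_seed(21, {
    x <- rand_grid(6, 6, 2)
    params <- list(W = protoseg:::he_conv(3, 3, 2, 3), b = stats::rnorm(3),
                   W1 = protoseg:::he_conv(1, 1, 3, 2), b1 = stats::rnorm(2),
                   Wd = matrix(stats::rnorm(2 * 4), 2, 4), bd = stats::rnorm(4),
                   x = x)
    grad_check(function(tape, pn) {
      h <- protoseg:::ag_conv2d(tape, pn$x, pn$W, pn$b, pad = 1L)
      h <- protoseg:::ag_sigmoid(tape, h)       # smooth nonlinearity for FD
      h <- protoseg:::ag_avgpool(tape, h, 2L)
      h <- protoseg:::ag_conv2d(tape, h, pn$W1, pn$b1, pad = 0L)
      h <- protoseg:::ag_upsample(tape, h, 2L)
      v <- protoseg:::ag_gap(tape, h)
      v <- protoseg:::ag_dense(tape, v, pn$Wd, pn$bd)
      protoseg:::ag_bce_logit(tape, protoseg:::ag_dense(
        tape, v, matrix(1, 4, 1), 0), 1)
    }, params)
  })
})

test_that("cosine, pooling-matrix and allocation gradients match finite differences", {
  withr::with_seed(22, {
    Fq <- rand_grid(4, 4, 3)
    Fs <- rand_grid(4, 4, 3)
    A <- protoseg:::window_partition(4, 4, 0.5)$A
    y <- rand_mask(4, 4)
    params <- list(Fq = Fq, Fs = Fs)
    grad_check(function(tape, pn) {
      P <- protoseg:::ag_pool_mat(tape, pn$Fs, A)
      D <- protoseg:::ag_cosine(tape, pn$Fq, P, 20)
      PM <- protoseg:::ag_alloc(tape, D)
      Db <- protoseg:::ag_cosine(tape, pn$Fq, P, 10)
      PMb <- protoseg:::ag_alloc(tape, Db)
      protoseg:::ag_softmax_ce(tape, PM, PMb, y)
    }, params, n_probe = 5)
  })
})

test_that("guide and concat gradients match finite differences", {
  withr::with_seed(23, {
    Fs <- rand_grid(4, 4, 2)
    Fq <- rand_grid(4, 4, 2)
    A <- matrix(0, 16, 2)
    A[1:8, 1] <- 1 / 8; A[9:16, 2] <- 1 / 8
    Dfix <- array(stats::rnorm(4 * 4 * 2), c(4, 4, 2))  # fixed selection
    y <- rand_mask(4, 4)
    params <- list(Fs = Fs, Fq = Fq)
    grad_check(function(tape, pn) {
      P <- protoseg:::ag_pool_mat(tape, pn$Fs, A)
      FG <- protoseg:::ag_guide(tape, Dfix, P)
      M <- protoseg:::ag_concat_c(tape, list(FG, pn$Fq))
      s <- protoseg:::ag_gap(tape, M)
      protoseg:::ag_bce_logit(tape, protoseg:::ag_dense(
        tape, s, matrix(1, 4, 1), 0.3), 0)
    }, params, n_probe = 4)
  })
})

test_that("straight-through threshold passes gradients unchanged", {
  tape <- protoseg:::ag_tape()
  p <- protoseg:::ag_leaf(tape, matrix(c(0.2, 0.8, 0.5, 0.6), 2, 2))
  h <- protoseg:::ag_hard_st(tape, p)
  expect_equal(protoseg:::ag_value(h), matrix(c(0, 1, 0, 1), 2, 2))
  s <- protoseg:::ag_node(tape, sum(protoseg:::ag_value(h)), list(h),
                          function(g) list(matrix(g, 2, 2)))
  protoseg:::ag_backward(tape, s)
  expect_equal(protoseg:::ag_grad(p), matrix(1, 2, 2))
})

test_that("tape forward agrees with the plain prototype pipeline", {
  withr::with_seed(24, {
    m <- tiny_test_model(seed = 3, fpn = FALSE, gnet = FALSE)
    ep <- toy_episode(4)
    bb <- protoseg:::prefixed(m$params$gen, "bb.")
    Fs <- backbone_forward(ep$support_image, m$backbone, params = bb)
    Fq <- backbone_forward(ep$query_image, m$backbone, params = bb)
    mf <- protoseg:::mask_to_feature(ep$support_mask, 4)
    P_fg <- local_prototypes(Fs, mf, m$window_scale, m$tau)
    S <- similarity_stack(Fq, P_fg, m$alpha_scale)
    PM <- allocate_probability(S)
    tape <- protoseg:::ag_tape()
    fwd <- protoseg:::proto_branch_tape(
      tape, protoseg:::ag_leaf(tape, Fs), protoseg:::ag_leaf(tape, Fq),
      ep$support_mask, m)
    expect_equal(protoseg:::ag_value(fwd$PM_fg), PM, tolerance = 1e-10)
  })
})

test_that("full generator objective gradient matches finite differences on l_pro", {
  # restricted to the smooth prototype branch: fixed masks, no argmax paths
  withr::with_seed(25, {
    m <- tiny_test_model(seed = 5, fpn = FALSE, gnet = FALSE)
    ep <- toy_episode(6)
    params <- m$params$gen
    f <- function(p) {
      tape <- protoseg:::ag_tape()
      pn <- protoseg:::ag_leaves(tape, p)
      Fs <- protoseg:::backbone_forward_tape(tape, protoseg:::prefixed(pn, "bb."),
                                             ep$support_image, m$backbone)
      Fq <- protoseg:::backbone_forward_tape(tape, protoseg:::prefixed(pn, "bb."),
                                             ep$query_image, m$backbone)
      fwd <- protoseg:::proto_branch_tape(tape, Fs, Fq, ep$support_mask, m)
      list(tape = tape,
           loss = protoseg:::ag_softmax_ce(tape, fwd$PM_fg_img, fwd$PM_bg_img,
                                           ep$query_mask))
    }
    run <- f(params)
    protoseg:::ag_backward(run$tape, run$loss)
    grads <- lapply(protoseg:::ag_leaves(run$tape, params), function(x) NULL)
    scalar_f <- function(p) {
      r <- f(p)
      protoseg:::ag_value(r$loss)
    }
    # a fresh tape whose leaf gradients we read back
    tape <- protoseg:::ag_tape()
    pn <- protoseg:::ag_leaves(tape, params)
    Fs <- protoseg:::backbone_forward_tape(tape, protoseg:::prefixed(pn, "bb."),
                                           ep$support_image, m$backbone)
    Fq <- protoseg:::backbone_forward_tape(tape, protoseg:::prefixed(pn, "bb."),
                                           ep$query_image, m$backbone)
    fwd <- protoseg:::proto_branch_tape(tape, Fs, Fq, ep$support_mask, m)
    loss <- protoseg:::ag_softmax_ce(tape, fwd$PM_fg_img, fwd$PM_bg_img,
                                     ep$query_mask)
    protoseg:::ag_backward(tape, loss)
    for (nm in c("bb.c1.W", "bb.c2.W", "bb.c3.W", "bb.c1.b")) {
      g <- protoseg:::ag_grad(pn[[nm]])
      for (i in sample(length(params[[nm]]), 2)) {
        fd <- fd_grad(scalar_f, params, nm, i, h = 1e-5)
        # ReLU kinks can perturb FD slightly; modest tolerance
        expect_equal(g[i], fd, tolerance = 1e-3,
                     label = paste0("d l_pro/d ", nm, "[", i, "]"))
      }
    }
  })
})
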