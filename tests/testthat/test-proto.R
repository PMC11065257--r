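# Prototype mathematics against brute-force oracles.

test_that("local prototypes match exhaustive per-window means", {
  # frozen example: 4x4 grid with entries 1..16 row-major, half-size windows
  F_grid <- array(matrix(1:16, 4, 4, byrow = TRUE), c(4, 4, 1))
  ps <- local_prototypes(F_grid, matrix(1, 4, 4), window_scale = 0.5, tau = 0)
  expect_equal(sort(c(ps$vectors)), c(3.5, 5.5, 11.5, 13.5))
  expect_true(all(ps$kind == "local"))

  withr::with_seed(11, {
    for (rep in 1:30) {
      H <- sample(2:8, 1); W <- sample(2:8, 1); C <- sample(1:4, 1)
      alpha <- sample(c(1, 0.5, 0.25), 1)
      tau <- stats::runif(1, 0, 0.8)
      Fg <- rand_grid(H, W, C)
      M <- rand_mask(H, W)
      orc <- oracle_window_pool(Fg, M, alpha)
      keep <- which(orc$occ >= tau)
      got <- local_prototypes(Fg, M, alpha, tau)
      if (length(keep) > 0) {
        expect_equal(unname(got$vectors), unname(orc$vectors[keep, , drop = FALSE]),
                     tolerance = 1e-6)
        expect_equal(got$window, keep)
      } else {
        expect_equal(got$kind, "global")
        expect_equal(c(got$vectors), oracle_masked_pool(Fg, M), tolerance = 1e-6)
      }
    }
  })
})

test_that("window scale 1 with a full mask reduces to the global mean", {
  Fg <- rand_grid(6, 6, 3)
  ps <- local_prototypes(Fg, matrix(1, 6, 6), window_scale = 1, tau = 0)
  expect_equal(nrow(ps$vectors), 1L)
  expect_equal(c(ps$vectors), apply(Fg, 3, mean), tolerance = 1e-12)
})

test_that("constant features give constant prototypes", {
  Fg <- array(0.7, c(8, 8, 2))
  ps <- local_prototypes(Fg, matrix(1, 8, 8), window_scale = 0.5, tau = 0.9)
  expect_equal(nrow(ps$vectors), 4L)
  expect_true(all(abs(ps$vectors - 0.7) < 1e-12))
})

test_that("masked global prototype matches loop summation", {
  withr::with_seed(12, {
    Fg <- rand_grid(8, 8, 2)
    M <- rand_mask(8, 8)
    expect_equal(masked_global_prototype(Fg, M), oracle_masked_pool(Fg, M),
                 tolerance = 1e-6)
  })
  # single pixel: exactly that pixel's feature vector
  Fg <- rand_grid(5, 5, 3)
  M <- matrix(0, 5, 5); M[2, 4] <- 1
  expect_equal(masked_global_prototype(Fg, M), Fg[2, 4, ])
  # uniform mask: overall spatial mean
  expect_equal(masked_global_prototype(Fg, matrix(1, 5, 5)),
               apply(Fg, 3, mean))
  expect_error(masked_global_prototype(Fg, matrix(0, 5, 5)), "positive")
})

test_that("cosine similarity stack is scaled, bounded, and exact on knowns", {
  v <- c(0.3, -1.2, 0.7)
  Fq <- array(0, c(1, 2, 3))
  Fq[1, 1, ] <- v
  Fq[1, 2, ] <- c(1, 0, 0)
  P <- rbind(v, c(0, 0, 2), c(1, 1, 0))
  S <- similarity_stack(Fq, P)
  expect_equal(S$maps[1, 1, 1], 20, tolerance = 1e-6)   # identical vectors
  expect_equal(S$maps[1, 2, 2], 0, tolerance = 1e-6)    # orthogonal
  expect_equal(S$maps[1, 2, 3], 20 / sqrt(2), tolerance = 1e-6)
  expect_true(all(abs(S$maps) <= 20 + 1e-9))
  # positive rescaling of the query leaves similarities unchanged
  S2 <- similarity_stack(Fq * 37.5, P)
  expect_equal(S2$maps, S$maps, tolerance = 1e-9)
})

test_that("prototype allocation is the softmax-weighted similarity average", {
  # singleton: identity
  D1 <- array(stats::rnorm(12), c(3, 4, 1))
  expect_equal(allocate_probability(D1), D1[, , 1])
  # equal maps: value preserved
  De <- array(1.7, c(2, 2, 3))
  expect_equal(allocate_probability(De), matrix(1.7, 2, 2))
  # frozen two-map value at one pixel
  D <- array(c(2, -2), c(1, 1, 2))
  sig <- exp(2) / (exp(2) + exp(-2))
  expect_equal(allocate_probability(D)[1, 1], 2 * sig - 2 * (1 - sig),
               tolerance = 1e-9)
  expect_equal(allocate_probability(D)[1, 1], 1.928055, tolerance = 1e-5)
  # randomized pixelwise oracle + convex-combination bound
  withr::with_seed(13, {
    for (rep in 1:20) {
      K <- sample(1:6, 1)
      D <- array(stats::rnorm(4 * 5 * K, sd = 8), c(4, 5, K))
      PM <- allocate_probability(D)
      for (r in 1:4) for (cl in 1:5) {
        expect_equal(PM[r, cl], oracle_alloc_pixel(D[r, cl, ]),
                     tolerance = 1e-8)
      }
      lo <- apply(D, c(1, 2), min); hi <- apply(D, c(1, 2), max)
      expect_true(all(PM >= lo - 1e-9 & PM <= hi + 1e-9))
    }
  })
})

test_that("guide features place the argmax prototype at each pixel", {
  P <- rbind(c(1, 0), c(0, 1), c(-1, 2))
  D <- array(stats::rnorm(6 * 7 * 3), c(6, 7, 3))
  FG <- guide_features(D, P)
  for (r in 1:6) for (cl in 1:7) {
    expect_equal(FG[r, cl, ], P[which.max(D[r, cl, ]), ])
  }
  # exact tie: lowest prototype index wins
  Dt <- array(1, c(1, 1, 3))
  expect_equal(guide_features(Dt, P)[1, 1, ], P[1, ])
  # K = 1: every pixel carries the lone prototype
  expect_true(all(guide_features(D[, , 1, drop = FALSE],
                                 P[1, , drop = FALSE])[, , 1] == 1))
})

test_that("merge_features concatenates guide, probability plane and query", {
  FG <- rand_grid(4, 4, 3)
  PM <- matrix(stats::rnorm(16), 4, 4)
  Fq <- rand_grid(4, 4, 5)
  Fm <- merge_features(FG, PM, Fq)
  expect_equal(dim(Fm), c(4, 4, 9))
  expect_equal(Fm[, , 1:3], FG)
  expect_equal(Fm[, , 4], PM)   # plane sits right after the guide channels
  expect_equal(Fm[, , 5:9], Fq)
  expect_error(merge_features(FG, matrix(0, 3, 3), Fq), "spatial")
})

test_that("final prediction is the pixelwise argmax with background ties", {
  fg <- matrix(stats::rnorm(20), 4, 5)
  bg <- matrix(stats::rnorm(20), 4, 5)
  m <- final_prediction(fg, bg)
  expect_equal(m, (fg > bg) * 1L, ignore_attr = TRUE)
  expect_true(all(final_prediction(bg + 1, bg) == 1))
  expect_true(all(final_prediction(bg, bg) == 0))
})

test_that("excluding every window reduces the pipeline to the global route", {
  withr::with_seed(14, {
    Fs <- rand_grid(8, 8, 3)
    Fq <- rand_grid(8, 8, 3)
    M <- rand_mask(8, 8, p = 0.2)
    # tau above every occupancy: the set must be the single Eq-2 prototype
    loc <- local_prototypes(Fs, M, window_scale = 0.25, tau = 1.1)
    expect_identical(loc$kind, "global")
    glob <- masked_global_prototype(Fs, M)
    expect_identical(c(loc$vectors), glob)
    S_loc <- similarity_stack(Fq, loc)
    S_glo <- similarity_stack(Fq, matrix(glob, 1))
    expect_identical(S_loc$maps, S_glo$maps)
    expect_identical(allocate_probability(S_loc), allocate_probability(S_glo))
  })
})

test_that("the debug dump writes one TIFF page per prototype plus two maps", {
  Fq <- rand_grid(8, 8, 3)
  P <- matrix(stats::rnorm(6), 2, 3)
  S <- similarity_stack(Fq, P)
  pm <- allocate_probability(S)
  path <- withr::local_tempfile(fileext = ".tif")
  write_debug_tiff(S, pm, -pm, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 4)
  expect_true(all(vapply(pages, function(p) all(p >= 0 & p <= 1), logical(1))))
})
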