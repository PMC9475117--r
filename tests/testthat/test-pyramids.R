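test_that("gaussian down-sampling halves sizes and preserves constants", {
  img <- array(stats::runif(128 * 256 * 3), c(128, 256, 3))
  dn <- gaussian_down(img)
  expect_equal(dim(dn), c(64L, 128L, 3L))
  cimg <- matrix(0.42, 32, 48)
  expect_equal(gaussian_down(cimg), matrix(0.42, 16, 24), tolerance = 1e-12)
  expect_error(gaussian_down(matrix(1, 1, 8)), "degenerate")
})

test_that("gaussian down-sampling equals brute-force separable convolution", {
  set.seed(11)
  m <- matrix(runif(16 * 20), 16, 20)
  # oracle: direct 2-d convolution with the outer binomial kernel and
  # mirrored (reflect-101) borders, then decimation by 2
  k1 <- c(1, 4, 6, 4, 1) / 16
  K <- outer(k1, k1)
  ref <- function(i, n) { i <- ifelse(i < 1, 2 - i, i); ifelse(i > n, 2 * n - i, i) }
  blur <- matrix(0, 16, 20)
  for (i in 1:16) for (j in 1:20) {
    acc <- 0
    for (a in -2:2) for (b in -2:2)
      acc <- acc + K[a + 3, b + 3] * m[ref(i + a, 16), ref(j + b, 20)]
    blur[i, j] <- acc
  }
  oracle <- matrix(0, 8, 10)
  for (i in 1:8) for (j in 1:10)
    oracle[i, j] <- mean(blur[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(gaussian_down(m), oracle, tolerance = 1e-12)
})

test_that("bilinear up-sampling interpolates rather than replicating", {
  expect_equal(bilinear_up(matrix(0.3, 4, 4), c(9, 9)), matrix(0.3, 9, 9),
               tolerance = 1e-12)
  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- bilinear_up(checker, c(4, 4))
  interior <- up[2:3, 2:3]
  expect_true(all(interior > 0 & interior < 1))
  expect_error(bilinear_up(matrix(0, 8, 8), c(4, 4)), "at least")
})

test_that("laplacian levels satisfy the band-pass identity and zero out constants", {
  img <- fixture_texture(9, c(64, 128))
  for (i in 0:2) {
    g <- img
    if (i > 0) for (k in seq_len(i)) g <- gaussian_down(g)
    oracle <- g - bilinear_up(gaussian_down(g), dim(g)[1:2])
    expect_equal(laplacian_level(img, i), oracle, tolerance = 1e-12)
  }
  const <- array(0.7, c(32, 32, 3))
  for (i in 0:2) expect_lt(max(abs(laplacian_level(const, i))), 1e-12)
})

test_that("collapsing a 5-level stack reconstructs the image exactly", {
  set.seed(21)
  img <- array(runif(128 * 256 * 3), c(128, 256, 3))
  st <- laplacian_pyramid(img, 5)
  expect_s3_class(st, "laplacian_stack")
  expect_lt(max(abs(collapse_laplacian(st) - img)), 1e-6)
})

test_that("fine laplacian energy is small for a pure low-frequency input", {
  blob <- outer(exp(-((1:64) - 32)^2 / 500), exp(-((1:64) - 32)^2 / 500))
  st <- laplacian_pyramid(blob, 4)
  fine <- sum(st$laplacians[[1]]^2)
  coarse <- sum(st$laplacians[[4]]^2)
  expect_lt(fine, 0.1 * coarse)
})

test_that("the fusion stack matches requested encoder scales exactly", {
  img <- fixture_texture(5, c(64, 64))
  scales <- list(c(64, 64), c(32, 32), c(16, 16), c(8, 8), c(4, 4), c(2, 2), c(1, 1))
  fs <- fusion_stack(img, scales)
  expect_length(fs, 7)
  for (k in 1:7) expect_equal(dim(fs[[k]])[1:2], as.integer(unlist(scales[[k]])))
  const_fs <- fusion_stack(array(0.5, c(64, 64, 3)), scales)
  for (f in const_fs) expect_lt(max(abs(f)), 1e-12)
  expect_identical(fs, fusion_stack(img, scales))
})
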