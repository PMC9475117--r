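test_that("bilinear sampling is exact at zero and integer disparities", {
  p <- fixture_pair(1, c(48, 96), d = 4)
  left <- p$left
  expect_identical(bilinear_sample(left, matrix(0, 48, 96), "right_from_left"), left)
  # integer shift oracle on the interior
  k <- 3
  w <- bilinear_sample(left, matrix(k, 48, 96), "right_from_left")
  expect_equal(w[, 1:(96 - k), ], left[, (k + 1):96, ], tolerance = 1e-14)
  expect_error(bilinear_sample(left, matrix(0, 10, 10)), "match")
})

test_that("the warp gradient w.r.t. disparity matches finite differences", {
  set.seed(5)
  img <- array(runif(12 * 20 * 3), c(12, 20, 3, 1))
  d0 <- array(runif(12 * 20) * 3 + 1, c(12, 20, 1, 1))
  dt <- endostereo:::ag_tensor(d0, requires_grad = TRUE)
  loss <- endostereo:::ag_mean(endostereo:::ag_sq(endostereo:::ag_warp_h(img, dt, -1)))
  endostereo:::ag_backward(loss)
  f <- function(dd) mean(endostereo:::cpp_warp_h_fwd(img, dd, -1)^2)
  idx <- cbind(c(3, 7, 10), c(5, 12, 18))
  for (r in seq_len(nrow(idx))) {
    dp <- d0; dm <- d0
    dp[idx[r, 1], idx[r, 2], 1, 1] <- dp[idx[r, 1], idx[r, 2], 1, 1] + 1e-6
    dm[idx[r, 1], idx[r, 2], 1, 1] <- dm[idx[r, 1], idx[r, 2], 1, 1] - 1e-6
    fd <- (f(dp) - f(dm)) / 2e-6
    expect_equal(dt$grad[idx[r, 1], idx[r, 2], 1, 1], fd, tolerance = 1e-4)
  }
  expect_gt(max(abs(dt$grad)), 0)
})

test_that("SSIM matches its closed forms and the brute-force oracle", {
  img <- fixture_texture(2, c(32, 48))
  expect_true(all(ssim_map(img, img) == 1))
  # constant images: variance terms vanish, closed form survives
  a <- array(0.2, c(16, 16, 3)); b <- array(0.4, c(16, 16, 3))
  c1 <- (0.01)^2
  expect_equal(ssim_map(a, b)[1, 1, 1], (2 * 0.2 * 0.4 + c1) / (0.2^2 + 0.4^2 + c1),
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:3) {
    x <- array(runif(20 * 24 * 3), c(20, 24, 3))
    y <- pmin(pmax(x + rnorm(length(x), 0, 0.1), 0), 1)
    expect_equal(ssim_map(x, y), ssim_oracle(x, y), tolerance = 1e-5)
  }
  expect_error(ssim_map(matrix(0, 2, 2), matrix(0, 2, 2), window = 5), "window")
})

test_that("the photometric error mixes SSIM and L1 as specified", {
  img <- fixture_texture(3, c(32, 32))
  expect_lt(max(photometric_error(img, img)), 1e-12)
  noisy <- pmin(pmax(img + 0.1, 0), 1)
  w0 <- loss_weights(alpha = 0)
  expect_equal(photometric_error(img, noisy, w0),
               apply(abs(img - noisy), c(1, 2), mean), tolerance = 1e-12)
  # constant images: combine both closed forms at alpha = 0.85
  a <- array(0.2, c(16, 16, 3)); b <- array(0.4, c(16, 16, 3))
  c1 <- 1e-4
  s <- (2 * 0.2 * 0.4 + c1) / (0.2^2 + 0.4^2 + c1)
  expected <- 0.85 / 2 * (1 - s) + 0.15 * 0.2
  expect_equal(photometric_error(a, b)[1, 1], expected, tolerance = 1e-10)
})

test_that("minimum reprojection and auto-masking follow their definitions", {
  set.seed(7)
  m1 <- matrix(runif(30), 5, 6)
  m2 <- matrix(runif(30), 5, 6)
  expect_identical(min_reprojection(list(m1)), m1)
  expect_equal(min_reprojection(list(m1, m1 * 0)), m1 * 0)
  expect_equal(min_reprojection(list(m1, m2)), pmin(m1, m2))
  expect_error(min_reprojection(list()), "at least")

  img <- fixture_texture(4, c(32, 48))
  # static pair: unwarped error is exactly zero, strict < fails everywhere
  mu <- auto_mask(img, list(img), list(bilinear_sample(img, matrix(2, 32, 48))))
  expect_true(all(mu == 0))
  # perfect warp vs a genuinely different source: everything kept
  other <- fixture_texture(5, c(32, 48))
  mu2 <- auto_mask(img, list(other), list(img))
  expect_true(all(mu2 == 1))
  expect_true(all(mu2 %in% c(0, 1)))
})

test_that("left-right consistency vanishes for constants and scores offsets", {
  z <- matrix(0, 16, 32)
  expect_equal(lr_consistency(z, z), 0)
  c2 <- matrix(2, 16, 32); c3 <- matrix(3, 16, 32)
  expect_equal(lr_consistency(c2, c2), 0)
  expect_equal(lr_consistency(c2, c3), 1.0)
  expect_equal(lr_consistency(c2, c3, side = "right"), 1.0)
})

test_that("edge-aware smoothness has the expected closed forms", {
  flat <- array(0.5, c(16, 32, 3))
  expect_equal(edge_smoothness(matrix(4, 16, 32), flat), 0)
  # linear ramp with slope g per pixel on a constant image -> g per axis term
  g <- 0.25
  ramp <- matrix(rep(g * (0:31), each = 16), 16, 32)
  expect_equal(edge_smoothness(ramp, flat), g, tolerance = 1e-12)
  # a disparity jump aligned with an image edge costs less than on a flat area
  djump <- matrix(0, 16, 32); djump <- djump; djump[, 17:32] <- 5
  edge_img <- flat; edge_img[, 17:32, ] <- 0.9
  expect_lt(edge_smoothness(djump, edge_img), edge_smoothness(djump, flat))
})

test_that("the total loss is the hand-computed per-scale combination", {
  mk <- function(pl, pr, ll, lr, sl, sr)
    list(photometric_left = pl, photometric_right = pr, lr_left = ll,
         lr_right = lr, smooth_left = sl, smooth_right = sr)
  per_scale <- list(mk(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), mk(0.2, 0.1, 0.1, 0.1, 0.2, 0.2))
  w <- loss_weights(lambda = 0.1)
  tl <- total_loss(per_scale, w)
  hand <- mean(c(0.1 + 0.2, 0.2 + 0.1)) +
    0.1 * (mean(c(0.3, 0.1)) + mean(c(0.4, 0.1)) + mean(c(0.5, 0.2)) + mean(c(0.6, 0.2)))
  expect_equal(tl$total, hand, tolerance = 1e-12)
  zero <- total_loss(list(mk(0, 0, 0, 0, 0, 0)), w)
  expect_equal(zero$total, 0)
  lam0 <- total_loss(per_scale, loss_weights(lambda = 0))
  expect_equal(lam0$total, mean(c(0.3, 0.3)))
})

test_that("the exhaustive photometric search recovers synthetic disparity", {
  p <- fixture_pair(11, c(48, 96), d = 4)
  est <- disparity_search_oracle(p$left, p$right, 0:8)
  interior <- est[5:44, 10:86]
  expect_equal(as.numeric(names(which.max(table(interior)))), 4)
  expect_gte(mean(abs(interior - 4) <= 1), 0.9)
  # identical eyes give zero offset
  est0 <- disparity_search_oracle(p$left, p$left, 0:4)
  expect_equal(as.numeric(names(which.max(table(est0)))), 0)
  # ramp disparity: recovered field tracks the truth
  ramp <- generate_disparity_field(disparity_spec("ramp", 8), c(48, 96))
  right_r <- render_right_view(p$left, ramp)
  est_r <- disparity_search_oracle(p$left, right_r, 0:9)
  inner <- 5:44
  expect_gt(stats::cor(as.vector(est_r[inner, 12:84]), as.vector(ramp[inner, 12:84])), 0.8)
})
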