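# Gradient correctness of the reverse-mode engine: every kernel's
# vector-Jacobian product is checked against central finite differences on
# small random problems.

ag <- function(v, rg = TRUE) endostereo:::ag_tensor(v, requires_grad = rg)

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  run <- function(xx, ww, bb) {
    t <- endostereo:::ag_mean(endostereo:::ag_sq(
      endostereo:::ag_conv2d(ag(xx), ag(ww), ag(bb), stride = 2L, pad = 1L)))
    t$value
  }
  xt <- ag(x); wt <- ag(w); bt <- ag(b)
  loss <- endostereo:::ag_mean(endostereo:::ag_sq(
    endostereo:::ag_conv2d(xt, wt, bt, stride = 2L, pad = 1L)))
  endostereo:::ag_backward(loss)
  expect_equal(xt$grad, num_grad(function(v) run(v, w, b), x), tolerance = 1e-5)
  expect_equal(wt$grad, num_grad(function(v) run(x, v, b), w), tolerance = 1e-5)
  expect_equal(as.vector(bt$grad), as.vector(num_grad(function(v) run(x, w, v), b)),
               tolerance = 1e-5)
})

test_that("transposed convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  run <- function(xx, ww) {
    t <- endostereo:::ag_mean(endostereo:::ag_sq(
      endostereo:::ag_tconv2d(ag(xx), ag(ww), NULL)))
    t$value
  }
  xt <- ag(x); wt <- ag(w)
  y <- endostereo:::ag_tconv2d(xt, wt, NULL)
  expect_equal(dim(endostereo:::ag_value(y)), c(8L, 10L, 2L, 2L))
  loss <- endostereo:::ag_mean(endostereo:::ag_sq(y))
  endostereo:::ag_backward(loss)
  expect_equal(xt$grad, num_grad(function(v) run(v, w), x), tolerance = 1e-5)
  expect_equal(wt$grad, num_grad(function(v) run(x, v), w), tolerance = 1e-5)
})

test_that("resampling, blurring and pooling gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(5 * 6 * 2 * 1), c(5, 6, 2, 1))
  cases <- list(
    up = function(t) endostereo:::ag_upsample(t, 9L, 11L),
    blur = function(t) endostereo:::ag_boxblur(t, 3L),
    gap = function(t) endostereo:::ag_global_avgpool(t),
    gmp = function(t) endostereo:::ag_global_maxpool(t),
    cmean = function(t) endostereo:::ag_channel_mean(t),
    cmax = function(t) endostereo:::ag_channel_max(t),
    dx = function(t) endostereo:::ag_diff_w(t),
    dy = function(t) endostereo:::ag_diff_h(t),
    slice = function(t) endostereo:::ag_slice_c(t, 2L)
  )
  for (nm in names(cases)) {
    op <- cases[[nm]]
    xt <- ag(x)
    loss <- endostereo:::ag_mean(endostereo:::ag_sq(op(xt)))
    endostereo:::ag_backward(loss)
    fd <- num_grad(function(v) {
      endostereo:::ag_mean(endostereo:::ag_sq(op(ag(v, FALSE))))$value
    }, x)
    expect_equal(xt$grad, fd, tolerance = 1e-5, label = nm)
  }
})

test_that("batch normalization gradients and statistics are correct", {
  set.seed(4)
  x <- array(rnorm(4 * 5 * 3 * 2, mean = 2, sd = 3), c(4, 5, 3, 2))
  st <- endostereo:::bn_state(3)
  gm <- ag(rep(1.5, 3)); bt <- ag(rep(0.3, 3))
  xt <- ag(x)
  y <- endostereo:::ag_batchnorm(xt, gm, bt, st, training = TRUE)
  yv <- endostereo:::ag_value(y)
  # normalized output has ~zero mean and gamma^2 variance per channel
  for (c in 1:3) {
    expect_equal(mean(yv[, , c, ]), 0.3, tolerance = 1e-8)
    expect_equal(stats::var(as.vector(yv[, , c, ])) * (39 / 40), 1.5^2, tolerance = 1e-3)
  }
  loss <- endostereo:::ag_mean(endostereo:::ag_sq(y))
  endostereo:::ag_backward(loss)
  run <- function(xx, gg, bb) {
    st2 <- endostereo:::bn_state(3)
    endostereo:::ag_mean(endostereo:::ag_sq(
      endostereo:::ag_batchnorm(ag(xx, FALSE), ag(gg, FALSE), ag(bb, FALSE),
                                st2, training = TRUE)))$value
  }
  expect_equal(xt$grad, num_grad(function(v) run(v, c(1.5, 1.5, 1.5), c(0.3, 0.3, 0.3)), x),
               tolerance = 1e-4)
  expect_equal(as.vector(gm$grad),
               as.vector(num_grad(function(v) run(x, v, c(0.3, 0.3, 0.3)), rep(1.5, 3))),
               tolerance = 1e-4)
})

test_that("gradient accumulates when a node feeds several consumers", {
  x <- ag(array(2, c(1, 1, 1, 1)))
  y <- endostereo:::ag_add(endostereo:::ag_sq(x), endostereo:::ag_smul(x, 3))
  loss <- endostereo:::ag_sum(y)
  endostereo:::ag_backward(loss)
  # d/dx (x^2 + 3x) = 2x + 3 = 7
  expect_equal(as.vector(x$grad), 7)
})

test_that("Adam steps reduce a simple convex objective deterministically", {
  p <- ag(array(c(5, -3), c(1, 1, 2, 1)))
  opt <- endostereo:::adam_init(list(p), lr = 0.1)
  vals <- numeric(50)
  for (k in 1:50) {
    endostereo:::ag_zero_grad(list(p))
    loss <- endostereo:::ag_mean(endostereo:::ag_sq(p))
    endostereo:::ag_backward(loss)
    opt <- endostereo:::adam_step(opt)
    vals[k] <- loss$value
  }
  expect_lt(vals[50], vals[1] / 10)
})
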