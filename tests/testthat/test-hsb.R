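test_that("HSB conserves channel bookkeeping and spatial shape", {
  set.seed(1)
  cfg <- hsb_config(s = 2)
  wts <- hsb_init(4, 4, cfg)
  f <- array(rnorm(8 * 10 * 4), c(8, 10, 4))
  out <- hsb_forward(f, cfg, wts)
  expect_equal(dim(out), c(8L, 10L, 4L))
  # designed width regardless of s, including odd splits
  for (s in 2:6) {
    cfgS <- hsb_config(s = s)
    wtsS <- hsb_init(7, 7, cfgS)
    fS <- array(rnorm(6 * 6 * 7), c(6, 6, 7))
    expect_equal(dim(hsb_forward(fS, cfgS, wtsS)), c(6L, 6L, 7L))
  }
})

test_that("HSB forward matches a hand-unrolled split/conv/concat oracle", {
  set.seed(5)
  cfg <- hsb_config(s = 3)
  C <- 6
  wts <- hsb_init(C, C, cfg)
  f <- array(rnorm(5 * 7 * C) * 0.5, c(5, 7, C))
  conv_ref <- function(x, w, b, pad) {
    d <- dim(x); kh <- dim(w)[1]; co <- dim(w)[4]
    out <- array(0, c(d[1], d[2], co))
    xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    for (cc in seq_len(co)) for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, cc] <- sum(xp[i:(i + kh - 1), j:(j + kh - 1), ] * w[, , , cc]) + b[cc]
    out
  }
  relu <- function(x) pmax(x, 0)
  # unroll: 1x1 pre, split (2,2,2), chain with carry = ceil(c/2)
  h <- relu(conv_ref(f, wts$pre$w$value, wts$pre$b$value, 0))
  x1 <- h[, , 1:2, drop = FALSE]
  x2 <- h[, , 3:4, drop = FALSE]
  x3 <- h[, , 5:6, drop = FALSE]
  y2 <- relu(conv_ref(x2, wts$convs[[1]]$w$value, wts$convs[[1]]$b$value, 1))
  carry <- y2[, , 1, drop = FALSE]  # ceil(2/2) = 1 carried
  emit2 <- y2[, , 2, drop = FALSE]
  y3 <- relu(conv_ref(abind_c(x3, carry), wts$convs[[2]]$w$value, wts$convs[[2]]$b$value, 1))
  concat <- abind_c(abind_c(x1, emit2), y3)
  body <- conv_ref(concat, wts$post$w$value, wts$post$b$value, 0)
  oracle <- relu(body + f)  # cin == cout, identity residual
  expect_equal(hsb_forward(f, cfg, wts), oracle, tolerance = 1e-10)
})

test_that("counted HSB parameters stay below the standard-convolution count", {
  for (s in 2:6) {
    pc <- hsb_param_count(3, 4, s)
    expect_lt(pc$p_hsb, pc$p_standard)
    expect_equal(pc$p_standard, 9 * s^2 * 16)
  }
  expect_equal(hsb_param_count(3, 4, 5)$p_standard, 3600)
  # monotone nondecreasing in the group width
  counts <- sapply(c(2, 4, 8), function(w) hsb_param_count(3, w, 4)$p_hsb)
  expect_true(all(diff(counts) >= 0))
})

test_that("the disparity network emits four bounded scales of the right widths", {
  spec <- disp_net_spec(width_multiplier = 1/8, max_disparity_fraction = 0.3)
  net <- build_disp_net(spec, seed = 2)
  x <- array(runif(128 * 256 * 3), c(128, 256, 3, 1))
  outs <- endostereo:::forward_disp(net, x, training = FALSE)
  expect_length(outs, 4)
  widths <- sapply(outs, function(o) dim(endostereo:::ag_value(o$dl))[2])
  expect_equal(widths, c(32, 64, 128, 256))
  for (o in outs) {
    wsc <- dim(endostereo:::ag_value(o$dl))[2]
    dl <- endostereo:::ag_value(o$dl)
    dr <- endostereo:::ag_value(o$dr)
    expect_gte(min(dl), 0)
    expect_lte(max(dl), 0.3 * wsc)
    expect_gte(min(dr), 0)
    expect_lte(max(dr), 0.3 * wsc)
  }
  # repeated forward passes are identical (pure function of weights + input)
  outs2 <- endostereo:::forward_disp(net, x, training = FALSE)
  expect_identical(endostereo:::ag_value(outs[[4]]$dl),
                   endostereo:::ag_value(outs2[[4]]$dl))
})

test_that("a zeroed disparity head sits at half the sigmoid range", {
  spec <- disp_net_spec(width_multiplier = 1/8, max_disparity_fraction = 0.2)
  net <- build_disp_net(spec, seed = 3)
  for (j in 2:5) {
    hd <- net$params$dec[[j]]$head
    hd$w$value <- hd$w$value * 0
    hd$b$value <- hd$b$value * 0
  }
  x <- array(runif(64 * 128 * 3), c(64, 128, 3, 1))
  outs <- endostereo:::forward_disp(net, x, training = FALSE)
  for (o in outs) {
    wsc <- dim(endostereo:::ag_value(o$dl))[2]
    expect_equal(max(abs(endostereo:::ag_value(o$dl) - 0.5 * 0.2 * wsc)), 0,
                 tolerance = 1e-12)
  }
})

test_that("predicted disparity is nonnegative with the input's shape", {
  net <- build_disp_net(disp_net_spec(width_multiplier = 1/8), seed = 4)
  left <- fixture_texture(2, c(64, 128))
  d <- predict_disparity(net, left)
  expect_equal(dim(d), c(64L, 128L))
  expect_gte(min(d), 0)
  # non-multiple-of-32 sizes are handled by internal resize
  left2 <- fixture_texture(2, c(50, 90))
  d2 <- predict_disparity(net, left2)
  expect_equal(dim(d2), c(50L, 90L))
})
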