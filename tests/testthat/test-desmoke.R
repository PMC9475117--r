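test_that("the desmoking forward pass is a same-size autoencoder", {
  spec <- desmoke_net_spec(width_multiplier = 1/8)
  net <- build_desmoke_net(spec, seed = 1)
  x <- array(runif(64 * 128 * 3 * 2), c(64, 128, 3, 2))
  out <- endostereo:::ag_value(endostereo:::forward_desmoke(net, x))
  expect_equal(dim(out), c(64L, 128L, 3L, 2L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
})

test_that("the parameter count is a pure function of the spec", {
  spec <- desmoke_net_spec(width_multiplier = 1/8)
  n1 <- endostereo:::nn_param_count(build_desmoke_net(spec, seed = 1)$params)
  n2 <- endostereo:::nn_param_count(build_desmoke_net(spec, seed = 99)$params)
  expect_identical(n1, n2)
  expect_identical(unname(coef(build_desmoke_net(spec, seed = 5))[["parameters"]]), n1)
})

test_that("disabling Laplacian injection shrinks the first group input by 3 channels", {
  on <- build_desmoke_net(desmoke_net_spec(width_multiplier = 1/8), seed = 1)
  off <- build_desmoke_net(desmoke_net_spec(width_multiplier = 1/8,
                                            laplacian_injection = FALSE), seed = 1)
  cin_on <- dim(on$params$enc[[1]]$c1$w$value)[3]
  cin_off <- dim(off$params$enc[[1]]$c1$w$value)[3]
  expect_equal(cin_on - cin_off, 3L)
})

test_that("the L1 loss follows its arithmetic and symmetry contracts", {
  a <- fixture_texture(1, c(32, 32))
  expect_equal(desmoke_loss(a, a)$sum, 0)
  b <- array(0.1, c(2, 2, 3)); z <- array(0, c(2, 2, 3))
  expect_equal(desmoke_loss(z, b)$sum, 1.2)
  set.seed(2)
  x <- array(runif(2 * 2 * 3), c(2, 2, 3)); y <- array(runif(2 * 2 * 3), c(2, 2, 3))
  expect_equal(desmoke_loss(x, y)$sum, sum(abs(x - y)))
  expect_equal(desmoke_loss(x, y)$sum, desmoke_loss(y, x)$sum)
  # permutation invariance over pixels
  perm <- sample(12)
  xp <- array(as.vector(x)[perm], dim(x)); yp <- array(as.vector(y)[perm], dim(y))
  expect_equal(desmoke_loss(xp, yp)$sum, desmoke_loss(x, y)$sum)
  expect_error(desmoke_loss(x, array(0, c(3, 3, 3))), "match")
})

test_that("zero-epoch training returns the initialized network unchanged", {
  cleans <- lapply(1:4, function(i) fixture_texture(i, c(32, 32)))
  pairs <- fog_dataset(cleans, "light", seed = 2)
  cfg <- train_config(input_size = c(32, 32), epochs = 0, seed = 3)
  net0 <- train_desmoke(pairs, desmoke_net_spec(width_multiplier = 1/8), cfg)
  ref <- build_desmoke_net(desmoke_net_spec(width_multiplier = 1/8), seed = 3)
  expect_false(net0$trained)
  expect_identical(net0$params$head$w$value, ref$params$head$w$value)
})

test_that("training is deterministic and desmoke() honors shape contracts", {
  cleans <- lapply(1:8, function(i) fixture_texture(i, c(32, 32)))
  pairs <- fog_dataset(cleans, "light", seed = 5)
  cfg <- train_config(input_size = c(32, 32), epochs = 2, batch_size = 4,
                      learning_rate = 1e-3, seed = 7)
  n1 <- train_desmoke(pairs, desmoke_net_spec(width_multiplier = 1/8), cfg)
  n2 <- train_desmoke(pairs, desmoke_net_spec(width_multiplier = 1/8), cfg)
  expect_identical(n1$history, n2$history)
  out <- desmoke(n1, pairs[[1]]$fogged)
  expect_equal(dim(out), c(32L, 32L, 3L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  # other sizes are resized through the network and back
  big <- fixture_texture(9, c(48, 64))
  out2 <- desmoke(n1, big)
  expect_equal(dim(out2), c(48L, 64L, 3L))
  expect_identical(out2, predict(n1, big))
})
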