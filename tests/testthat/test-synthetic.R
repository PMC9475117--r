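test_that("tissue textures honor their range, shape and determinism contracts", {
  spec <- texture_spec(seed = 1, shape = c(128, 256))
  img <- generate_tissue_texture(spec)
  expect_equal(dim(img), c(128L, 256L, 3L))
  expect_gte(min(img), 0)
  expect_lte(max(img), 1)
  expect_identical(img, generate_tissue_texture(spec))
  expect_error(texture_spec(shape = c(16, 64)), "32")
})

test_that("more octaves add detail without shrinking overall contrast", {
  s3 <- generate_tissue_texture(texture_spec(seed = 5, shape = c(64, 96), octaves = 3))
  s1 <- generate_tissue_texture(texture_spec(seed = 5, shape = c(64, 96), octaves = 1))
  expect_gt(mean(abs(s3 - s1)), 0)
  expect_gte(sd(s3), sd(s1))
})

test_that("disparity fields match their analytic definitions", {
  const <- generate_disparity_field(disparity_spec("constant", 4), c(64, 128))
  expect_true(all(const == 4))
  ramp <- generate_disparity_field(disparity_spec("ramp", 8), c(32, 64))
  expect_equal(ramp[, 1], rep(0, 32))
  expect_equal(ramp[, 64], rep(8, 32))
  expect_true(all(apply(ramp, 1, function(r) all(diff(r) >= 0))))
  blob <- generate_disparity_field(disparity_spec("blob", 6), c(40, 80))
  expect_lte(max(blob), 6)
  expect_lt(max(abs(c(blob[1, ], blob[40, ], blob[, 1], blob[, 80]))), 1e-12)
  expect_error(generate_disparity_field(disparity_spec("constant", 40), c(64, 128)),
               "W/4")
})

test_that("rendering the right view is an exact index shift for integer disparity", {
  left <- fixture_texture(3, c(48, 96))
  expect_identical(render_right_view(left, matrix(0, 48, 96)), left)
  d3 <- matrix(3, 48, 96)
  right <- render_right_view(left, d3)
  expect_equal(right[, 1:(96 - 3), ], left[, 4:96, ], tolerance = 1e-14)
})

test_that("half-pixel disparity averages the two integer-shift neighbours", {
  left <- fixture_texture(4, c(32, 64))
  right <- render_right_view(left, matrix(2.5, 32, 64))
  oracle <- 0.5 * left[, 3:63, ] + 0.5 * left[, 4:64, ]
  expect_equal(right[, 1:61, ], oracle, tolerance = 1e-12)
})

test_that("dataset generation is deterministic and tracks smoke levels", {
  a <- make_stereo_dataset(4, texture_spec(shape = c(48, 96)),
                           disparity_spec("constant", 3), "none", seed = 7)
  b <- make_stereo_dataset(4, texture_spec(shape = c(48, 96)),
                           disparity_spec("constant", 3), "none", seed = 7)
  expect_identical(a, b)
  for (s in a) expect_identical(s$clean, s$left)
  dense <- make_stereo_dataset(4, texture_spec(shape = c(48, 96)),
                               disparity_spec("constant", 3), "dense", seed = 7)
  for (s in dense) expect_gt(mean(s$left), mean(s$clean))
})

test_that("written datasets round-trip through PNG/PFM/manifest", {
  dir <- withr::local_tempdir()
  samples <- make_stereo_dataset(2, texture_spec(shape = c(48, 96)),
                                 disparity_spec("ramp", 5), "none", seed = 3)
  write_stereo_dataset(samples, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man, 2)
  d <- read_pfm(file.path(dir, man[[1]]$gt_disparity))
  expect_equal(d, samples[[1]]$gt_disparity, tolerance = 1e-6)
  img <- read_image_rgb(file.path(dir, man[[1]]$left))
  expect_equal(img, samples[[1]]$left, tolerance = 1 / 255)
})
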