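## Synthetic stereo-endoscopy fixtures: tissue-like textures, analytic
## disparity fields, and right views rendered by horizontal warping, so the
## desmoking and disparity stages are testable with known ground truth.

#' Specification of a procedural tissue texture
#'
#' Multi-octave value noise over a reddish base color, with dark
#' curvilinear "vessel" strokes.  The same spec always produces the same
#' image.
#'
#' @param seed integer RNG seed.
#' @param shape `c(H, W)` in pixels, both at least 32.
#' @param octaves number of noise octaves (>= 1); higher adds finer detail.
#' @param vessel_count number of dark vessel strokes (>= 0).
#' @param color_base RGB triple in `[0, 1]`, the mean tissue color.
#' @return an object of class `texture_spec`.
#' @export
texture_spec <- function(seed = 1L, shape = c(128L, 256L), octaves = 4L,
                         vessel_count = 6L, color_base = c(0.62, 0.30, 0.24)) {
  if (length(shape) != 2L || any(shape < 32L))
    stop("texture shape must be at least 32 x 32", call. = FALSE)
  stopifnot(octaves >= 1L, vessel_count >= 0L,
            length(color_base) == 3L, all(color_base >= 0), all(color_base <= 1))
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 octaves = as.integer(octaves),
                 vessel_count = as.integer(vessel_count),
                 color_base = as.numeric(color_base)),
            class = "texture_spec")
}

## multi-octave value noise in roughly [-0.5, 0.5] * amplitude sum
value_noise <- function(H, W, octaves, base_res = 4L, persistence = 0.6) {
  acc <- matrix(0, H, W)
  amp <- 1
  for (o in seq_len(octaves)) {
    res <- base_res * 2L^(o - 1L)
    gh <- min(res, H)
    gw <- min(res, W)
    g <- matrix(stats::runif(gh * gw) - 0.5, gh, gw)
    up <- cpp_resize_bilinear(array(g, c(gh, gw, 1L, 1L)), H, W)
    acc <- acc + amp * matrix(up, H, W)
    amp <- amp * persistence
  }
  acc
}

## stamp a dark stroke along a random quadratic Bezier curve
stamp_vessel <- function(mask, width_px = 1.6, depth = 0.55) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(stats::runif(6), 3L, 2L) %*% diag(c(H, W))
  t <- seq(0, 1, length.out = 4L * max(H, W))
  b <- outer((1 - t)^2, p[1, ]) + outer(2 * t * (1 - t), p[2, ]) + outer(t^2, p[3, ])
  r <- ceiling(2 * width_px)
  for (k in seq_along(t)) {
    cy <- b[k, 1]; cx <- b[k, 2]
    ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    if (!length(ys) || !length(xs)) next
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    mask[ys, xs] <- pmax(mask[ys, xs], depth * exp(-d2 / (2 * width_px^2)))
  }
  mask
}

#' Generate a tissue-like RGB texture
#'
#' @param spec a [texture_spec()].
#' @return (H, W, 3) array in `[0, 1]`, deterministic per spec.
#' @export
generate_tissue_texture <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  with_seed(spec$seed, {
    base <- value_noise(H, W, spec$octaves)
    ## mild per-channel decorrelation so color carries information
    chroma <- value_noise(H, W, max(1L, spec$octaves - 1L))
    vessels <- matrix(0, H, W)
    if (spec$vessel_count > 0L)
      for (v in seq_len(spec$vessel_count)) vessels <- stamp_vessel(vessels)
    img <- array(0, c(H, W, 3L))
    gains <- c(1, 0.85, 0.7)
    for (c in 1:3) {
      ch <- spec$color_base[c] * (1 + 1.1 * base + 0.35 * gains[c] * chroma)
      img[, , c] <- ch * (1 - vessels)
    }
    clip01(img)
  })
}

#' Specification of a ground-truth disparity field
#'
#' @param kind one of `"constant"`, `"ramp"`, `"blob"`.
#' @param magnitude peak disparity in pixels (> 0); all generated values lie
#'   in `[0, magnitude]` and the field is horizontal-only.
#' @param seed integer (recorded for provenance; the three kinds are analytic).
#' @return an object of class `disparity_spec`.
#' @export
disparity_spec <- function(kind = c("constant", "ramp", "blob"),
                           magnitude = 4, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(magnitude > 0)
  structure(list(kind = kind, magnitude = as.numeric(magnitude),
                 seed = as.integer(seed)),
            class = "disparity_spec")
}

#' Generate a disparity field
#'
#' @param spec a [disparity_spec()].
#' @param shape `c(H, W)` of the target field.
#' @return H x W matrix of nonnegative disparities (pixels).  `constant` is
#'   uniform at `magnitude`; `ramp` rises linearly 0 to `magnitude` left to
#'   right; `blob` is a smooth bump, zero on the borders.
#' @export
generate_disparity_field <- function(spec, shape) {
  stopifnot(inherits(spec, "disparity_spec"), length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (spec$magnitude >= W / 4)
    stop("disparity magnitude must be below W/4 to keep warps valid", call. = FALSE)
  switch(spec$kind,
    constant = matrix(spec$magnitude, H, W),
    ramp = matrix(rep(spec$magnitude * (seq_len(W) - 1) / (W - 1), each = H), H, W),
    blob = {
      ry <- sin(pi * (seq_len(H) - 1) / (H - 1))
      rx <- sin(pi * (seq_len(W) - 1) / (W - 1))
      spec$magnitude * outer(ry^2, rx^2)
    })
}

#' Render the right view of a stereo pair from the left view and disparity
#'
#' Uses the package-wide sign convention `right(x) = left(x + d)`, `d >= 0`:
#' the right image samples the left image at horizontally displaced
#' coordinates through bilinear interpolation with edge clamping (backward
#' warping, so no holes; a simplification relative to true occlusion).
#'
#' @param left (H, W, 3) image.
#' @param d H x W nonnegative disparity (pixels), below `W/4`.
#' @return the rendered right view, (H, W, 3) in `[0, 1]`.
#' @export
render_right_view <- function(left, d) {
  check_image(left)
  if (!is.matrix(d) || !all(dim(d) == dim(left)[1:2]))
    stop("disparity shape must match the image", call. = FALSE)
  if (min(d) < 0 || max(d) >= ncol(d) / 4)
    stop("disparity must be nonnegative and below W/4", call. = FALSE)
  clip01(from_batch1(cpp_warp_h_fwd(as_batch1(left), disp_as_batch1(d), 1)))
}

#' A single synthetic stereo sample
#' @keywords internal
stereo_sample <- function(left, right, gt_disparity = NULL, clean = NULL) {
  stopifnot(all(dim(left) == dim(right)))
  if (!is.null(gt_disparity))
    stopifnot(all(dim(gt_disparity) == dim(left)[1:2]))
  structure(list(left = left, right = right,
                 gt_disparity = gt_disparity, clean = clean),
            class = "stereo_sample")
}

#' Generate a synthetic stereo-endoscopy dataset
#'
#' Each sample draws a fresh tissue texture (per-sample seed derived from
#' `seed`), renders the right view from the requested disparity field, and
#' optionally composites procedural smoke onto both eyes.  Ground-truth
#' disparity and the clean (smoke-free) left frame are always retained.
#'
#' @param n number of samples (>= 1).
#' @param texture a [texture_spec()] (its seed is re-derived per sample).
#' @param disparity a [disparity_spec()].
#' @param smoke_level `"none"`, `"light"`, or `"dense"`.
#' @param seed master seed controlling the whole dataset.
#' @return list of `stereo_sample` objects.
#' @export
make_stereo_dataset <- function(n, texture = texture_spec(),
                                disparity = disparity_spec(),
                                smoke_level = c("none", "light", "dense"),
                                seed = 1L) {
  stopifnot(n >= 1L)
  smoke_level <- match.arg(smoke_level)
  seeds <- derive_seeds(seed, 3L * n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tsp <- texture
    tsp$seed <- seeds[3L * i - 2L]
    left <- generate_tissue_texture(tsp)
    dsp <- disparity
    dsp$seed <- seeds[3L * i - 1L]
    d <- generate_disparity_field(dsp, tsp$shape)
    right <- render_right_view(left, d)
    clean <- left
    if (smoke_level != "none") {
      fl <- fog_image(left, level = smoke_level, seed = seeds[3L * i])
      ## the same smoke field degrades both eyes
      right <- fl$apply(right)
      left <- fl$fogged
    }
    out[[i]] <- stereo_sample(left, right, gt_disparity = d, clean = clean)
  }
  out
}

#' Write a stereo dataset to disk
#'
#' PNG images, PFM ground-truth disparity and a JSON manifest of seeds and
#' shapes.
#'
#' @param samples list of `stereo_sample` objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_stereo_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    base <- sprintf("sample_%03d", i)
    write_image_rgb(s$left, file.path(dir, paste0(base, "_left.png")))
    write_image_rgb(s$right, file.path(dir, paste0(base, "_right.png")))
    entry <- list(left = paste0(base, "_left.png"),
                  right = paste0(base, "_right.png"),
                  shape = dim(s$left)[1:2])
    if (!is.null(s$gt_disparity)) {
      write_pfm(s$gt_disparity, file.path(dir, paste0(base, "_disp.pfm")))
      entry$gt_disparity <- paste0(base, "_disp.pfm")
    }
    if (!is.null(s$clean)) {
      write_image_rgb(s$clean, file.path(dir, paste0(base, "_clean.png")))
      entry$clean <- paste0(base, "_clean.png")
    }
    manifest[[i]] <- entry
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
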