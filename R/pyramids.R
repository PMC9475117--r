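## Gaussian / Laplacian pyramids with bilinear up-sampling.
##
## Blur kernel: separable binomial [1,4,6,4,1]/16 (the standard Burt-Adelson
## choice, exactly normalized) with reflective padding so borders do not
## darken.  A Laplacian level is L_i = G_i - up(down(G_i)); collapsing the
## stack therefore reconstructs the input exactly by construction.

## separable 5-tap binomial blur of one channel (matrix), reflect padding
binomial_blur5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  H <- nrow(m); W <- ncol(m)
  ## reflect-pad by 2 on each side (edge mirror without repeating the edge
  ## when possible; degenerate tiny sizes fall back to edge replication)
  ridx <- function(n) {
    i <- c(3, 2, seq_len(n), n - 1, n - 2)
    i[i < 1] <- 1; i[i > n] <- n
    i
  }
  mp <- m[ridx(H), ridx(W), drop = FALSE]
  ## rows
  acc <- matrix(0, H, W + 4)
  for (t in 1:5) acc <- acc + k[t] * mp[(t - 1) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in 1:5) out <- out + k[t] * acc[, (t - 1) + seq_len(W), drop = FALSE]
  out
}

apply_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  d <- dim(img)
  out <- NULL
  for (c in seq_len(d[3])) {
    r <- f(matrix(img[, , c], d[1], d[2]))
    if (is.null(out)) out <- array(0, c(dim(r), d[3]))
    out[, , c] <- r
  }
  out
}

#' Gaussian down-sampling (one pyramid step)
#'
#' 5-tap binomial blur followed by decimation by 2 (floor-half output
#' sizes).  Constant images map to the same constant because the kernel is
#' exactly normalized.
#'
#' @param image (H, W, C) array or H x W matrix, H and W at least 2.
#' @return image at floor-half resolution.
#' @export
gaussian_down <- function(image) {
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (any(d < 2L)) stop("cannot down-sample a degenerate 1-pixel axis", call. = FALSE)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  ## decimation through the same half-pixel-center bilinear convention the
  ## up-sampler uses, so down/up round trips stay spatially aligned (for
  ## even sizes this is a 2 x 2 block average of the blurred image)
  apply_channels(image, function(m) {
    matrix(cpp_resize_bilinear(array(binomial_blur5(m), c(d[1], d[2], 1L, 1L)),
                               oh, ow), oh, ow)
  })
}

#' Bilinear up-sampling to a target shape
#'
#' Four-neighbor bilinear interpolation (half-pixel centers), replacing
#' nearest-neighbor so up-sampled levels show no mosaic blocking; constant
#' images map to the same constant.
#'
#' @param image (H, W, C) array or matrix.
#' @param target_shape `c(H', W')`, both at least the source size.
#' @return resized image.
#' @export
bilinear_up <- function(image, target_shape) {
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (any(target_shape < d))
    stop("target must be at least the source size in both dimensions", call. = FALSE)
  apply_channels(image, function(m) {
    matrix(cpp_resize_bilinear(array(m, c(dim(m), 1L, 1L)),
                               as.integer(target_shape[1]),
                               as.integer(target_shape[2])),
           target_shape[1], target_shape[2])
  })
}

#' Build a Gaussian/Laplacian pyramid
#'
#' @param image (H, W, C) array or matrix.
#' @param n_levels number of Laplacian levels.
#' @return object of class `laplacian_stack` with `gaussians` (levels
#'   `G_0 ... G_n`, `G_0` the input) and `laplacians` (`L_0 ... L_{n-1}`,
#'   each the band-pass residual at its Gaussian's size).
#' @export
laplacian_pyramid <- function(image, n_levels) {
  stopifnot(n_levels >= 1L)
  gaussians <- list(image)
  laplacians <- vector("list", n_levels)
  for (i in seq_len(n_levels)) {
    g <- gaussians[[i]]
    dn <- gaussian_down(g)
    gaussians[[i + 1L]] <- dn
    dg <- if (is.matrix(g)) dim(g) else dim(g)[1:2]
    laplacians[[i]] <- g - bilinear_up(dn, dg)
  }
  structure(list(gaussians = gaussians, laplacians = laplacians,
                 n_levels = as.integer(n_levels)),
            class = "laplacian_stack")
}

#' One Laplacian band-pass level
#'
#' `L_i = G_i - up(down(G_i))`: the level-`i` Gaussian minus its blurred,
#' decimated and bilinearly re-expanded self.
#'
#' @param image input image (level 0).
#' @param i level index (0-based).
#' @return the band-pass image at level `i`'s size.
#' @export
laplacian_level <- function(image, i) {
  g <- image
  if (i > 0L) for (k in seq_len(i)) g <- gaussian_down(g)
  dg <- if (is.matrix(g)) dim(g) else dim(g)[1:2]
  g - bilinear_up(gaussian_down(g), dg)
}

#' Collapse a Laplacian stack back to the original image
#'
#' Iteratively up-samples the coarsest Gaussian and adds each Laplacian;
#' exact by construction.
#'
#' @param stack a `laplacian_stack`.
#' @return the reconstructed level-0 image.
#' @export
collapse_laplacian <- function(stack) {
  stopifnot(inherits(stack, "laplacian_stack"))
  n <- stack$n_levels
  recon <- stack$gaussians[[n + 1L]]
  for (i in rev(seq_len(n))) {
    g <- stack$gaussians[[i]]
    dg <- if (is.matrix(g)) dim(g) else dim(g)[1:2]
    recon <- stack$laplacians[[i]] + bilinear_up(recon, dg)
  }
  recon
}

#' Per-scale Laplacian fusion images for the desmoking encoder
#'
#' One band-pass image per encoder scale, resized bilinearly to match that
#' scale exactly (needed because a 256 x 128 input with seven halvings hits
#' non-power-of-two sizes), ready for channel concatenation with the
#' encoder features.
#'
#' @param image (H, W, C) input frame.
#' @param encoder_scales list of `c(H_i, W_i)` shapes, strictly decreasing.
#' @return list of images, one per requested scale.
#' @export
fusion_stack <- function(image, encoder_scales) {
  ns <- length(encoder_scales)
  stopifnot(ns >= 1L)
  for (k in seq_len(ns - 1L))
    if (any(unlist(encoder_scales[[k + 1L]]) > unlist(encoder_scales[[k]])))
      stop("encoder scales must be non-increasing", call. = FALSE)
  out <- vector("list", ns)
  g <- image
  for (k in seq_len(ns)) {
    dg <- if (is.matrix(g)) dim(g) else dim(g)[1:2]
    ## a single-pixel axis carries no band-pass detail
    lap <- if (any(dg < 2L)) g * 0 else g - bilinear_up(gaussian_down(g), dg)
    tgt <- as.integer(unlist(encoder_scales[[k]]))
    out[[k]] <- if (all(dg == tgt)) lap else apply_channels(lap, function(m) {
      matrix(cpp_resize_bilinear(array(m, c(dim(m), 1L, 1L)), tgt[1], tgt[2]),
             tgt[1], tgt[2])
    })
    if (k < ns && all(dg >= 2L)) g <- gaussian_down(g)
  }
  out
}
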