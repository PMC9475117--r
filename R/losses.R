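## Differentiable bilinear sampling and the self-supervised stereo loss
## stack: SSIM+L1 photometric reprojection with auto-masking, left-right
## disparity consistency, edge-aware smoothness, and their per-scale
## combination.
##
## Sign convention (package-wide): right(x) = left(x + d), d >= 0.  A left
## pixel at column j therefore matches the right image at column j - d^l(j);
## the left view is reconstructed by sampling the right image at j - d^l and
## the right view by sampling the left image at j + d^r.

#' Loss weights for self-supervised disparity training
#'
#' @param alpha mix between SSIM and L1 in the photometric error
#'   (`alpha = 0.85`).
#' @param lambda weight on the consistency + smoothness block.  The default
#'   0.1 keeps the photometric term dominant, the usual regime in
#'   self-supervised stereo.
#' @param automask_enabled apply the binary reprojection auto-mask to the
#'   photometric terms?
#' @param ssim_window odd box-window size for the local SSIM statistics.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.85, lambda = 0.1, automask_enabled = TRUE,
                         ssim_window = 3L) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0, ssim_window %% 2L == 1L)
  structure(list(alpha = alpha, lambda = lambda,
                 automask_enabled = isTRUE(automask_enabled),
                 ssim_window = as.integer(ssim_window)),
            class = "loss_weights")
}

#' Differentiable horizontal bilinear sampling (STN warp)
#'
#' Samples `source` at horizontally displaced coordinates, taking the
#' weighted sum of the two horizontal neighbors of each sample point, with
#' edge clamping; exact at integer coordinates.
#'
#' @param source (H, W, 3) image or H x W matrix.
#' @param d H x W disparity in pixels.
#' @param direction `"right_from_left"` samples at `x + d` (synthesizes the
#'   right view from the left); `"left_from_right"` samples at `x - d`.
#' @return warped image, same shape as `source`.
#' @export
bilinear_sample <- function(source, d,
                            direction = c("right_from_left", "left_from_right")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "right_from_left") 1 else -1
  was_matrix <- is.matrix(source)
  src <- if (was_matrix) array(source, c(dim(source), 1L, 1L)) else as_batch1(source)
  if (!all(dim(src)[1:2] == dim(d)))
    stop("source and disparity shapes must match", call. = FALSE)
  out <- cpp_warp_h_fwd(src, disp_as_batch1(d), sgn)
  if (was_matrix) matrix(out, nrow(source), ncol(source)) else from_batch1(out)
}

## local statistics for SSIM on an (H,W,C,N) ag tensor or array
ssim_ag <- function(x, y, window = 3L, L = 1, k1 = 0.01, k2 = 0.03) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mx <- ag_boxblur(x, window); my <- ag_boxblur(y, window)
  mx2 <- ag_sq(mx); my2 <- ag_sq(my)
  mxy <- ag_mul(mx, my)
  sx2 <- ag_sub(ag_boxblur(ag_sq(x), window), mx2)
  sy2 <- ag_sub(ag_boxblur(ag_sq(y), window), my2)
  sxy <- ag_sub(ag_boxblur(ag_mul(x, y), window), mxy)
  num <- ag_mul(ag_addc(ag_smul(mxy, 2), c1), ag_addc(ag_smul(sxy, 2), c2))
  den <- ag_mul(ag_addc(ag_add(mx2, my2), c1), ag_addc(ag_add(sx2, sy2), c2))
  ag_divide(num, den)
}

## two small helpers used only by the loss stack
ag_addc <- function(x, k) {
  v <- ag_value(x)
  ag_op(v + k, list(x), function(g) list(g))
}
ag_divide <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  y <- av / bv
  ag_op(y, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

#' Per-pixel structural similarity map
#'
#' Sliding-window SSIM with box-filter local statistics (window truncated
#' and renormalized at borders), constants `c1 = (k1 L)^2`,
#' `c2 = (k2 L)^2`, `c3 = c2 / 2` (the standard simplification collapsing
#' the luminance/contrast/structure product to the two-term form).
#'
#' @param x,y (H, W, C) images or matrices of the same shape.
#' @param window odd window size (default 3); must not exceed the image.
#' @param L declared dynamic range (1 for float images, 255 for 8-bit).
#' @return per-pixel, per-channel SSIM values (<= 1), same shape as `x`.
#' @export
ssim_map <- function(x, y, window = 3L, L = 1) {
  if (!all(dim(x) == dim(y))) stop("shapes must match", call. = FALSE)
  d <- if (is.matrix(x)) c(dim(x), 1L) else dim(x)
  if (window > min(d[1], d[2]))
    stop("SSIM window larger than the image", call. = FALSE)
  xa <- array(x, c(d, 1L)); ya <- array(y, c(d, 1L))
  out <- ag_value(ssim_ag(xa, ya, window = window, L = L))
  if (is.matrix(x)) matrix(out, d[1], d[2]) else array(out, d)
}

## channel-mean per-pixel photometric error on ag tensors -> (H,W,1,N)
photometric_ag <- function(target, recon, w) {
  s <- ssim_ag(target, recon, window = w$ssim_window)
  ssim_term <- ag_channel_mean(ag_smul(ag_addc(ag_smul(s, -1), 1), 0.5 * w$alpha))
  l1_term <- ag_smul(ag_channel_mean(ag_abs(ag_sub(target, recon))), 1 - w$alpha)
  ag_add(ssim_term, l1_term)
}

#' Per-pixel photometric reconstruction error
#'
#' `pe = (alpha/2) (1 - SSIM) + (1 - alpha) |target - reconstructed|`,
#' channel-averaged; nonnegative, zero for identical images.
#'
#' @param target,reconstructed (H, W, 3) images.
#' @param w a [loss_weights()].
#' @return H x W error map.
#' @export
photometric_error <- function(target, reconstructed, w = loss_weights()) {
  if (!all(dim(target) == dim(reconstructed))) stop("shapes must match", call. = FALSE)
  pe <- photometric_ag(as_batch1(target), as_batch1(reconstructed), w)
  matrix(ag_value(pe), dim(target)[1], dim(target)[2])
}

#' Minimum reprojection error
#'
#' Elementwise minimum over candidate per-pixel error maps (one per source
#' view); with a single stereo source this degenerates to that map.
#'
#' @param errors nonempty list of equal-shaped error maps.
#' @return elementwise-minimum map.
#' @export
min_reprojection <- function(errors) {
  if (!length(errors)) stop("need at least one error map", call. = FALSE)
  Reduce(pmin, errors)
}

#' Binary reprojection auto-mask
#'
#' `mu = 1` where the minimum warped-reprojection error is strictly below
#' the minimum error against the unwarped source frames, else 0 (ties give
#' 0); static or textureless pixels are thereby excluded from the
#' photometric loss.
#'
#' @param target (H, W, 3) target view.
#' @param sources list of unwarped source views.
#' @param warped list of warped reconstructions (same length).
#' @param w a [loss_weights()].
#' @return H x W binary (0/1) matrix.
#' @export
auto_mask <- function(target, sources, warped, w = loss_weights()) {
  stopifnot(length(sources) == length(warped), length(sources) >= 1L)
  pe_w <- min_reprojection(lapply(warped, function(s) photometric_error(target, s, w)))
  pe_s <- min_reprojection(lapply(sources, function(s) photometric_error(target, s, w)))
  (pe_w < pe_s) * 1
}

#' Left-right disparity consistency loss
#'
#' Mean absolute difference between one eye's disparity and the other
#' eye's disparity sampled at the disparity-projected coordinate (bilinear,
#' edge-clamped): for the left loss, `| d^l(j) - d^r(j - d^l(j)) |`.
#'
#' @param d_l,d_r H x W left/right disparity maps (pixels).
#' @param side `"left"` or `"right"`: which eye's consistency to compute.
#' @return scalar mean consistency error.
#' @export
lr_consistency <- function(d_l, d_r, side = c("left", "right")) {
  side <- match.arg(side)
  if (!all(dim(d_l) == dim(d_r))) stop("shapes must match", call. = FALSE)
  if (side == "left") {
    proj <- bilinear_sample(d_r, d_l, "left_from_right")
    mean(abs(d_l - proj))
  } else {
    proj <- bilinear_sample(d_l, d_r, "right_from_left")
    mean(abs(d_r - proj))
  }
}

#' Edge-aware disparity smoothness loss
#'
#' Mean of first-order disparity gradients weighted by `exp(-|grad I|)`
#' (image gradients reduced over channels by mean absolute value), so
#' disparity jumps are cheap across image edges and expensive on flat
#' regions.
#'
#' @param d H x W disparity map.
#' @param I (H, W, 3) image sharing its spatial shape.
#' @return scalar loss.
#' @export
edge_smoothness <- function(d, I) {
  stopifnot(all(dim(d) == dim(I)[1:2]))
  dx_d <- abs(d[, -1, drop = FALSE] - d[, -ncol(d), drop = FALSE])
  dy_d <- abs(d[-1, , drop = FALSE] - d[-nrow(d), , drop = FALSE])
  gx_i <- apply(abs(I[, -1, , drop = FALSE] - I[, -ncol(d), , drop = FALSE]), c(1, 2), mean)
  gy_i <- apply(abs(I[-1, , , drop = FALSE] - I[-nrow(d), , , drop = FALSE]), c(1, 2), mean)
  mean(dx_d * exp(-gx_i)) + mean(dy_d * exp(-gy_i))
}

#' Combine per-scale loss components into the total training loss
#'
#' Per scale: masked photometric left + right terms plus
#' `lambda * (lr_left + lr_right + smooth_left + smooth_right)`; the
#' auto-mask weights only the photometric terms.  Scales are averaged.
#'
#' @param per_scale list (one entry per scale) of named scalar components
#'   `photometric_left`, `photometric_right`, `lr_left`, `lr_right`,
#'   `smooth_left`, `smooth_right` (photometric entries already
#'   mask-aggregated).
#' @param w a [loss_weights()].
#' @return list of class `loss_terms`: the averaged components and `total`.
#' @export
total_loss <- function(per_scale, w = loss_weights()) {
  stopifnot(length(per_scale) >= 1L)
  get_mean <- function(name)
    mean(vapply(per_scale, function(s) s[[name]], numeric(1)))
  comp <- list(photometric_left = get_mean("photometric_left"),
               photometric_right = get_mean("photometric_right"),
               lr_left = get_mean("lr_left"), lr_right = get_mean("lr_right"),
               smooth_left = get_mean("smooth_left"),
               smooth_right = get_mean("smooth_right"))
  comp$total <- comp$photometric_left + comp$photometric_right +
    w$lambda * (comp$lr_left + comp$lr_right + comp$smooth_left + comp$smooth_right)
  structure(comp, class = "loss_terms")
}

#' Exhaustive photometric disparity search (non-learning oracle)
#'
#' For each candidate constant disparity, reconstructs the left view from
#' the right, scores the photometric error, box-aggregates it, and takes
#' the per-pixel argmin.  A training-free sanity check of the photometric
#' objective.
#'
#' @param left,right (H, W, 3) stereo pair.
#' @param d_candidates finite vector of candidate disparities (pixels).
#' @param w a [loss_weights()].
#' @param agg_window box window for cost aggregation (odd).
#' @return H x W disparity map picking the per-pixel best candidate.
#' @export
disparity_search_oracle <- function(left, right, d_candidates,
                                    w = loss_weights(), agg_window = 9L) {
  stopifnot(length(d_candidates) >= 1L)
  H <- dim(left)[1]; W <- dim(left)[2]
  best_cost <- matrix(Inf, H, W)
  best_d <- matrix(d_candidates[1], H, W)
  for (dc in d_candidates) {
    recon <- bilinear_sample(right, matrix(dc, H, W), "left_from_right")
    pe <- photometric_error(left, recon, w)
    pe <- matrix(cpp_boxblur(array(pe, c(H, W, 1L, 1L)), as.integer(agg_window), FALSE), H, W)
    upd <- pe < best_cost
    best_cost[upd] <- pe[upd]
    best_d[upd] <- dc
  }
  best_d
}
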