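## Color-difference (red/cyan anaglyph) 3D rendering: the red channel is
## resampled through the (gain-scaled) disparity toward the virtual right
## viewpoint while the blue and green channels stay untouched, so the result
## viewed through red/cyan glasses carries the depth cue with minimal color
## loss.

#' Anaglyph rendering configuration
#'
#' @param disparity_gain display amplification of the parallax (> 0);
#'   1 keeps the geometric disparity.
#' @param fill_strategy `"clamp"` keeps edge-clamped samples;
#'   `"inpaint-nearest"` overwrites pixels resampled from out of frame with
#'   the nearest valid pixel in the same row.
#' @param direction warp the red channel toward the virtual `"right"`
#'   (default, matching the rendering convention of the stereo generator)
#'   or `"left"` viewpoint.
#' @return object of class `anaglyph_config`.
#' @export
anaglyph_config <- function(disparity_gain = 1, fill_strategy = c("clamp", "inpaint-nearest"),
                            direction = c("right", "left")) {
  stopifnot(disparity_gain > 0)
  structure(list(disparity_gain = disparity_gain,
                 fill_strategy = match.arg(fill_strategy),
                 direction = match.arg(direction)),
            class = "anaglyph_config")
}

#' Fill pixels marked invalid after resampling
#'
#' @param channel H x W matrix.
#' @param validity_mask logical H x W matrix, `FALSE` where the sample came
#'   from out of frame.
#' @param strategy `"clamp"` (leave edge-clamped values) or
#'   `"inpaint-nearest"` (copy the nearest valid pixel per row).
#' @return the filled channel; no invalid pixels remain.
#' @export
hole_fill <- function(channel, validity_mask, strategy = c("clamp", "inpaint-nearest")) {
  strategy <- match.arg(strategy)
  if (strategy == "clamp" || all(validity_mask)) return(channel)
  for (i in seq_len(nrow(channel))) {
    bad <- which(!validity_mask[i, ])
    good <- which(validity_mask[i, ])
    if (!length(bad)) next
    if (!length(good)) next
    for (j in bad) channel[i, j] <- channel[i, good[which.min(abs(good - j))]]
  }
  channel
}

#' Render a color-difference (anaglyph) 3D frame
#'
#' @param image (H, W, 3) source frame.
#' @param d H x W nonnegative disparity map (pixels).
#' @param cfg an [anaglyph_config()].
#' @return (H, W, 3) anaglyph: red resampled through `gain * d`, green and
#'   blue bit-identical to the input.  Zero disparity returns the input
#'   exactly.
#' @export
make_anaglyph <- function(image, d, cfg = anaglyph_config()) {
  check_image(image)
  if (!all(dim(d) == dim(image)[1:2]))
    stop("disparity shape must match the image", call. = FALSE)
  sgn <- if (cfg$direction == "right") 1 else -1
  dg <- cfg$disparity_gain * d
  red <- matrix(cpp_warp_h_fwd(array(image[, , 1], c(dim(d), 1L, 1L)),
                               disp_as_batch1(dg), sgn),
                nrow(d), ncol(d))
  if (cfg$fill_strategy == "inpaint-nearest") {
    xs <- matrix(rep(seq_len(ncol(d)) - 1, each = nrow(d)), nrow(d)) + sgn * dg
    valid <- xs >= 0 & xs <= ncol(d) - 1
    red <- hole_fill(red, valid, "inpaint-nearest")
  }
  out <- image
  out[, , 1] <- clip01(red)
  out
}
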