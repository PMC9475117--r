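## Image containers and file I/O.
##
## Images are numeric arrays with dim (H, W, 3), values in [0, 1].
## Disparity fields are numeric H x W matrices in pixels.

#' Validate an RGB image array
#' @param img object to check.
#' @return the image, invisibly; errors if not an (H, W, 3) array in [0, 1].
#' @keywords internal
check_image <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an (H, W, 3) image array", call. = FALSE)
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("image values must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## lift (H,W,3) -> (H,W,3,1) and back, for the C++ kernels
as_batch1 <- function(img) array(img, c(dim(img)[1], dim(img)[2], dim(img)[3], 1L))
from_batch1 <- function(x) array(x, dim(x)[1:3])
disp_as_batch1 <- function(d) array(d, c(nrow(d), ncol(d), 1L, 1L))

#' Read an RGB image from a PNG file
#'
#' @param path file path.
#' @return an (H, W, 3) array in `[0, 1]`; gray images are replicated to
#'   three channels and any alpha channel is dropped.
#' @export
read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB image to an 8-bit PNG file
#'
#' @param img (H, W, 3) array in `[0, 1]`.
#' @param path output file path.
#' @export
write_image_rgb <- function(img, path) {
  check_image(clip01(img))
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Write a disparity field as a PFM (portable float map) file
#'
#' Single-channel little-endian Middlebury PFM; rows are stored
#' bottom-to-top as the format requires.
#'
#' @param d H x W numeric matrix (disparity in pixels).
#' @param path output path.
#' @export
write_pfm <- function(d, path) {
  stopifnot(is.matrix(d))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", paste(ncol(d), nrow(d)), "-1.0"), con, sep = "\n")
  ## bottom-to-top rows, left-to-right within a row
  vals <- as.vector(t(d[rev(seq_len(nrow(d))), , drop = FALSE]))
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a single-channel PFM disparity file
#'
#' @param path input path.
#' @return H x W numeric matrix.
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readLines(con, n = 3L)
  if (hdr[1] != "Pf") stop("only single-channel (Pf) PFM files are supported")
  wh <- as.integer(strsplit(trimws(hdr[2]), "\\s+")[[1]])
  scale <- as.numeric(hdr[3])
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, numeric(), n = wh[1] * wh[2], size = 4L, endian = endian)
  m <- matrix(vals, nrow = wh[2], ncol = wh[1], byrow = TRUE)
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Resize an RGB image with bilinear interpolation
#'
#' Half-pixel-center (align-corners-false) convention; used both to shrink
#' frames to the network input size and to restore predictions.
#'
#' @param img (H, W, 3) array.
#' @param h,w target size.
#' @return resized (h, w, 3) array.
#' @export
resize_image <- function(img, h, w) {
  check_image(img)
  clip01(from_batch1(cpp_resize_bilinear(as_batch1(img), as.integer(h), as.integer(w))))
}

## evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

## derive per-item child seeds (< 2^31) from a master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
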