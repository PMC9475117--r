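## Quantitative image and disparity evaluation: PSNR, global SSIM,
## disparity MAE/RMSE, and batch reports.

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(MAX^2 / MSE)` with the mean squared error taken over
#' all pixels and channels; identical images give `Inf`.
#'
#' @param reference,test images (or matrices) of equal shape.
#' @param max_value declared dynamic range (1 for float images, 255 for
#'   8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!all(dim(reference) == dim(test))) stop("shapes must match", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Global structural similarity index
#'
#' Mean of the per-pixel [ssim_map()]; shares its 3x3 box-window
#' convention, so equals 1 exactly iff the images are identical.
#'
#' @inheritParams ssim_map
#' @return scalar SSIM (<= 1).
#' @export
ssim_index <- function(x, y, window = 3L, L = 1) {
  mean(ssim_map(x, y, window = window, L = L))
}

#' Disparity error metrics
#'
#' @param pred,truth H x W disparity maps (pixels).
#' @param valid_mask optional logical/0-1 matrix restricting the evaluated
#'   pixels; must keep at least one pixel.
#' @param mm_per_px optional calibration factor converting pixels to mm.
#' @return list with `mae` and `rmse` (pixels, or mm if a factor is given).
#' @export
disparity_errors <- function(pred, truth, valid_mask = NULL, mm_per_px = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("shapes must match", call. = FALSE)
  err <- pred - truth
  if (!is.null(valid_mask)) {
    keep <- as.logical(valid_mask)
    if (!any(keep)) stop("valid mask excludes every pixel", call. = FALSE)
    err <- err[keep]
  }
  k <- if (is.null(mm_per_px)) 1 else mm_per_px
  list(mae = mean(abs(err)) * k, rmse = sqrt(mean(err^2)) * k)
}

#' Evaluate a batch of image (and optionally disparity) predictions
#'
#' @param references,tests equal-length lists of images (e.g. clean frames
#'   and desmoked outputs).
#' @param pred_disp,true_disp optional equal-length lists of disparity maps.
#' @param max_value image dynamic range declared in the report.
#' @param mm_per_px optional disparity calibration factor.
#' @param out_json optional path; when given, the report is written as JSON.
#' @return a `metrics_report` list: per-image psnr/ssim with mean and sd,
#'   disparity mae/rmse, and `n_images`.
#' @export
evaluate_batch <- function(references, tests, pred_disp = NULL, true_disp = NULL,
                           max_value = 1, mm_per_px = NULL, out_json = NULL) {
  stopifnot(length(references) >= 1L, length(references) == length(tests))
  ps <- mapply(psnr, references, tests, MoreArgs = list(max_value = max_value))
  ss <- mapply(ssim_index, references, tests)
  rep <- list(n_images = length(references),
              max_value = max_value,
              psnr = list(values = ps, mean = mean(ps), sd = stats::sd(ps)),
              ssim = list(values = ss, mean = mean(ss), sd = stats::sd(ss)))
  if (!is.null(pred_disp)) {
    stopifnot(length(pred_disp) == length(true_disp))
    de <- mapply(function(p, t) unlist(disparity_errors(p, t, mm_per_px = mm_per_px)),
                 pred_disp, true_disp)
    rep$disparity <- list(units = if (is.null(mm_per_px)) "px" else "mm",
                          mae = list(values = de["mae", ], mean = mean(de["mae", ]),
                                     sd = stats::sd(de["mae", ])),
                          rmse = list(values = de["rmse", ], mean = mean(de["rmse", ]),
                                      sd = stats::sd(de["rmse", ])))
  }
  class(rep) <- "metrics_report"
  if (!is.null(out_json))
    jsonlite::write_json(unclass(rep), out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics over %d image(s) (MAX = %g):\n", x$n_images, x$max_value))
  cat(sprintf("  PSNR: %.3f dB (sd %.3f)\n", x$psnr$mean, x$psnr$sd %||% NA))
  cat(sprintf("  SSIM: %.4f (sd %.4f)\n", x$ssim$mean, x$ssim$sd %||% NA))
  if (!is.null(x$disparity))
    cat(sprintf("  disparity MAE %.3f %s, RMSE %.3f %s\n",
                x$disparity$mae$mean, x$disparity$units,
                x$disparity$rmse$mean, x$disparity$units))
  invisible(x)
}
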