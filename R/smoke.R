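## Procedural surgical-smoke synthesis and compositing.
##
## Smoke is near-grayscale multi-octave turbulence shaped by a Gaussian
## falloff around a random center and scaled by a density parameter, then
## added to the clean frame and clipped ("light" = one pass; "dense" = a
## second independent pass applied to the light result).  Smoke is purely
## additive and independent of scene depth.

#' Smoke rendering parameters
#'
#' @param t_rand turbulence seed (scalar; offsets the noise octaves).
#' @param d_rand density in `(0, 1]`; the rendered field scales linearly
#'   with it, so `d_rand -> 0` yields vanishing smoke.
#' @param p_rand smoke center `c(x, y)` in normalized `[0, 1]^2` coordinates.
#' @param seed integer RNG seed; the same parameters always render the same
#'   field.
#' @return object of class `smoke_params`.
#' @export
smoke_params <- function(t_rand = 0, d_rand = 0.8, p_rand = c(0.5, 0.5),
                         seed = 1L) {
  stopifnot(d_rand > 0, d_rand <= 1,
            length(p_rand) == 2L, all(p_rand >= 0), all(p_rand <= 1))
  structure(list(t_rand = as.numeric(t_rand), d_rand = as.numeric(d_rand),
                 p_rand = as.numeric(p_rand), seed = as.integer(seed)),
            class = "smoke_params")
}

#' Render a semi-transparent smoke field
#'
#' @param params a [smoke_params()].
#' @param shape `c(H, W)` of the target field.
#' @return (H, W, 3) array in `[0, 1]`: near-grayscale (equal channels),
#'   brightest near `p_rand`, decaying with distance.
#' @export
render_smoke <- function(params, shape) {
  stopifnot(inherits(params, "smoke_params"), length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  with_seed(params$seed + as.integer(round(params$t_rand)) %% 1000L, {
    turb <- value_noise(H, W, octaves = 4L, base_res = 3L, persistence = 0.55)
    turb <- (turb - min(turb)) / max(1e-12, diff(range(turb)))
    cy <- params$p_rand[2] * (H - 1) + 1
    cx <- params$p_rand[1] * (W - 1) + 1
    sig2 <- (0.3 * max(H, W))^2
    fall <- exp(-(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)) / (2 * sig2))
    g <- params$d_rand * fall * (0.45 + 0.55 * turb)
    array(rep(clip01(g), 3L), c(H, W, 3L))
  })
}

#' Scalar smoke mask from an RGB smoke field
#'
#' Per-pixel luminance-weighted channel combination with weights
#' (0.30, 0.59, 0.11); the weights sum to 1, so a pure-white smoke pixel
#' maps to mask value 1.
#'
#' @param smoke (H, W, 3) smoke field in `[0, 1]`.
#' @return H x W matrix in `[0, 1]`.
#' @export
smoke_mask <- function(smoke) {
  d <- dim(smoke)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("smoke field must have three channels", call. = FALSE)
  matrix(0.3 * smoke[, , 1] + 0.59 * smoke[, , 2] + 0.11 * smoke[, , 3],
         d[1], d[2])
}

#' Composite smoke onto a clean frame
#'
#' Plain additive superposition clipped to `[0, 1]`; pixels with zero smoke
#' are untouched and increasing smoke never decreases any pixel value.
#'
#' @param clean (H, W, 3) clean image.
#' @param smoke (H, W, 3) smoke field.
#' @return fogged (H, W, 3) image.
#' @export
composite_smoke <- function(clean, smoke) {
  if (!all(dim(clean) == dim(smoke)))
    stop("clean and smoke shapes must match", call. = FALSE)
  clip01(clean + smoke)
}

## fog one image; returns the fogged frame plus a closure replaying the same
## smoke pass(es) on another frame (used to degrade both eyes identically)
fog_image <- function(img, level = c("light", "dense"), seed = 1L) {
  level <- match.arg(level)
  H <- dim(img)[1]; W <- dim(img)[2]
  n_pass <- if (level == "dense") 2L else 1L
  seeds <- derive_seeds(seed, 3L * n_pass)
  fields <- vector("list", n_pass)
  params <- vector("list", n_pass)
  for (p in seq_len(n_pass)) {
    pr <- with_seed(seeds[3L * p - 1L], stats::runif(2))
    dr <- with_seed(seeds[3L * p], 0.35 + 0.45 * stats::runif(1))
    params[[p]] <- smoke_params(t_rand = p, d_rand = dr, p_rand = pr,
                                seed = seeds[3L * p - 2L])
    fields[[p]] <- render_smoke(params[[p]], c(H, W))
  }
  apply_fog <- function(x) {
    for (f in fields) x <- composite_smoke(x, f)
    x
  }
  list(fogged = apply_fog(img), apply = apply_fog, params = params,
       mask = smoke_mask(Reduce(`+`, fields) |> clip01()))
}

#' Fog a set of clean frames at a given smoke level
#'
#' `light` applies one render+composite pass per image; `dense` applies a
#' second independent pass to the light result.  Clean frames pass through
#' unmodified as labels.
#'
#' @param cleans nonempty list of (H, W, 3) clean images.
#' @param level `"light"` or `"dense"`.
#' @param seed master seed; per-image seeds are derived from it.
#' @return list of `list(fogged, clean, params, mask)` pairs (the scalar
#'   smoke mask is recorded for inspection; the desmoking loss itself uses
#'   only images).
#' @export
fog_dataset <- function(cleans, level = c("light", "dense"), seed = 1L) {
  level <- match.arg(level)
  if (!length(cleans)) stop("need at least one clean frame", call. = FALSE)
  seeds <- derive_seeds(seed, length(cleans))
  lapply(seq_along(cleans), function(i) {
    f <- fog_image(cleans[[i]], level = level, seed = seeds[i])
    list(fogged = f$fogged, clean = cleans[[i]], params = f$params, mask = f$mask)
  })
}
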