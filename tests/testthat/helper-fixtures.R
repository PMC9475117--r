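# Shared fixtures, all generated in code at test time.

fixture_texture <- function(seed = 7, shape = c(48, 96), octaves = 4) {
  generate_tissue_texture(texture_spec(seed = seed, shape = shape, octaves = octaves))
}

fixture_pair <- function(seed = 7, shape = c(48, 96), d = 4) {
  left <- fixture_texture(seed, shape)
  disp <- generate_disparity_field(disparity_spec("constant", d), shape)
  list(left = left, right = render_right_view(left, disp), d = disp)
}

# brute-force sliding-window SSIM oracle: explicit three-term
# luminance * contrast * structure product with truncated box windows
ssim_oracle <- function(x, y, window = 3, L = 1, k1 = 0.01, k2 = 0.03) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2; c3 <- c2 / 2
  r <- (window - 1) / 2
  one <- function(xm, ym) {
    H <- nrow(xm); W <- ncol(xm)
    out <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      ys <- max(1, i - r):min(H, i + r)
      xs <- max(1, j - r):min(W, j + r)
      px <- xm[ys, xs]; py <- ym[ys, xs]
      mx <- mean(px); my <- mean(py)
      vx <- mean(px^2) - mx^2; vy <- mean(py^2) - my^2
      vx <- max(vx, 0); vy <- max(vy, 0)
      cxy <- mean(px * py) - mx * my
      sx <- sqrt(vx); sy <- sqrt(vy)
      l <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
      cc <- (2 * sx * sy + c2) / (vx + vy + c2)
      ss <- (cxy + c3) / (sx * sy + c3)
      out[i, j] <- l * cc * ss
    }
    out
  }
  if (is.matrix(x)) return(one(x, y))
  d <- dim(x)
  arr <- array(0, d)
  for (c in seq_len(d[3])) arr[, , c] <- one(x[, , c], y[, , c])
  arr
}

# concatenate two (H, W, C) arrays along the channel axis
abind_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}
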