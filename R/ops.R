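## Differentiable operations on (H, W, C, N) tensors.  Heavy kernels
## (convolution, resampling, warping, box filtering) live in src/kernels.cpp;
## elementwise work stays vectorized in R.

dim4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

## replicate a (1,1,C,N) array across pixels / a (H,W,1,N) array across channels
expand_channels <- function(s, H, W) {
  d <- dim(s)
  array(rep(as.vector(s), each = H * W), c(H, W, d[3], d[4]))
}
expand_spatial <- function(m, C) {
  m[, , rep(1L, C), , drop = FALSE]
}

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- ag_value(x); wv <- ag_value(w)
  y <- cpp_conv_fwd(xv, wv, as.integer(stride), as.integer(pad))
  dy_ <- dim(y)
  if (!is.null(b)) {
    bv <- ag_value(b)
    y <- y + rep(rep(bv, each = dy_[1] * dy_[2]), times = dy_[4])
    dim(y) <- dy_
  }
  dx_ <- dim(xv); dw_ <- dim(wv)
  ag_op(y, list(x, w, b), function(g) {
    dim(g) <- dy_
    list(
      if (is_ag(x) && x$requires)
        cpp_conv_bwd_data(g, wv, as.integer(stride), as.integer(pad), dx_[1], dx_[2]),
      if (is_ag(w) && w$requires)
        cpp_conv_bwd_weight(xv, g, as.integer(stride), as.integer(pad), dw_[1], dw_[2]),
      if (!is.null(b) && is_ag(b) && b$requires)
        rowSums(matrix(colSums(matrix(g, dy_[1] * dy_[2])), dy_[3], dy_[4]))
    )
  })
}

## transposed convolution; weight dim (kh, kw, C_out, C_in)
ag_tconv2d <- function(x, w, b = NULL, stride = 2L, pad = 1L, outpad = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  dx_ <- dim(xv); dw_ <- dim(wv)
  oh <- (dx_[1] - 1L) * stride - 2L * pad + dw_[1] + outpad
  ow <- (dx_[2] - 1L) * stride - 2L * pad + dw_[2] + outpad
  y <- cpp_conv_bwd_data(xv, wv, as.integer(stride), as.integer(pad), oh, ow)
  dy_ <- dim(y)
  if (!is.null(b)) {
    bv <- ag_value(b)
    y <- y + rep(rep(bv, each = dy_[1] * dy_[2]), times = dy_[4])
    dim(y) <- dy_
  }
  ag_op(y, list(x, w, b), function(g) {
    dim(g) <- dy_
    list(
      if (is_ag(x) && x$requires)
        cpp_conv_fwd(g, wv, as.integer(stride), as.integer(pad)),
      if (is_ag(w) && w$requires)
        cpp_conv_bwd_weight(g, xv, as.integer(stride), as.integer(pad), dw_[1], dw_[2]),
      if (!is.null(b) && is_ag(b) && b$requires)
        rowSums(matrix(colSums(matrix(g, dy_[1] * dy_[2])), dy_[3], dy_[4]))
    )
  })
}

ag_relu <- function(x) {
  v <- ag_value(x)
  y <- v
  y[y < 0] <- 0
  ag_op(y, list(x), function(g) list(g * (v > 0)))
}

ag_sigmoid <- function(x) {
  v <- ag_value(x)
  s <- 1 / (1 + exp(-v))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av + bv, list(a, b), function(g) {
    gb <- if (length(bv) == 1L && length(av) > 1L) sum(g) else g
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av - bv, list(a, b), function(g) {
    gb <- if (length(bv) == 1L && length(av) > 1L) -sum(g) else -g
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1L && length(bv) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(av) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

## multiply / add by a constant (no gradient through k)
ag_smul <- function(x, k) {
  v <- ag_value(x)
  ag_op(v * k, list(x), function(g) list(g * k))
}
ag_cmul <- function(x, k) ag_smul(x, k)

ag_sq <- function(x) {
  v <- ag_value(x)
  ag_op(v * v, list(x), function(g) list(2 * g * v))
}

ag_abs <- function(x) {
  v <- ag_value(x)
  ag_op(abs(v), list(x), function(g) list(g * sign(v)))
}

ag_mean <- function(x) {
  v <- ag_value(x)
  n <- length(v)
  dmn <- dim(v)
  ag_op(mean(v), list(x), function(g) {
    list(array(g / n, dmn %||% n))
  })
}

ag_sum <- function(x) {
  v <- ag_value(x)
  dmn <- dim(v)
  ag_op(sum(v), list(x), function(g) array(g, dmn %||% length(v)) |> list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## elementwise minimum of two tensors (used by minimum reprojection)
ag_min2 <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  m <- av <= bv
  ag_op(pmin(av, bv), list(a, b), function(g) list(g * m, g * !m))
}

## per-channel scaling: s has dim (1,1,C,N)
ag_scale_channels <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim4(xv)
  E <- expand_channels(sv, d[1], d[2])
  ag_op(xv * E, list(x, s), function(g) {
    ds <- colSums(matrix(g * xv, d[1] * d[2]))
    dim(ds) <- c(1L, 1L, d[3], d[4])
    list(g * E, ds)
  })
}

## per-pixel scaling: m has dim (H,W,1,N)
ag_scale_spatial <- function(x, m) {
  xv <- ag_value(x); mv <- ag_value(m)
  d <- dim4(xv)
  E <- expand_spatial(mv, d[3])
  S <- kronecker(diag(d[4]), rep(1, d[3]))
  ag_op(xv * E, list(x, m), function(g) {
    dm <- matrix(g * xv, d[1] * d[2], d[3] * d[4]) %*% S
    dim(dm) <- c(d[1], d[2], 1L, d[4])
    list(g * E, dm)
  })
}

## concatenate along the channel axis
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim4(vals[[1]])
  cs <- vapply(vals, function(v) dim4(v)[3], numeric(1))
  Cout <- as.integer(sum(cs))
  out <- array(0, c(d1[1], d1[2], Cout, d1[4]))
  off <- 0L
  for (v in vals) {
    cv <- dim(v)[3]
    out[, , (off + 1L):(off + cv), ] <- v
    off <- off + cv
  }
  ag_op(out, xs, function(g) {
    dim(g) <- c(d1[1], d1[2], Cout, d1[4])
    res <- vector("list", length(xs))
    off <- 0L
    for (k in seq_along(xs)) {
      cv <- cs[k]
      res[[k]] <- g[, , (off + 1L):(off + cv), , drop = FALSE]
      off <- off + cv
    }
    res
  })
}

ag_upsample <- function(x, oh, ow) {
  xv <- ag_value(x)
  d <- dim4(xv)
  y <- cpp_resize_bilinear(xv, as.integer(oh), as.integer(ow))
  ag_op(y, list(x), function(g) {
    dim(g) <- c(as.integer(oh), as.integer(ow), d[3], d[4])
    list(cpp_resize_bilinear_bwd(g, d[1], d[2]))
  })
}

ag_warp_h <- function(img, disp, sign) {
  iv <- ag_value(img); dv <- ag_value(disp)
  y <- cpp_warp_h_fwd(iv, dv, sign)
  ag_op(y, list(img, disp), function(g) {
    dim(g) <- dim(iv)
    r <- cpp_warp_h_bwd(iv, dv, sign, g)
    list(r$dimg, r$ddisp)
  })
}

ag_boxblur <- function(x, k = 3L) {
  xv <- ag_value(x)
  y <- cpp_boxblur(xv, as.integer(k), FALSE)
  ag_op(y, list(x), function(g) {
    dim(g) <- dim(xv)
    list(cpp_boxblur(g, as.integer(k), TRUE))
  })
}

ag_global_avgpool <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  y <- colMeans(matrix(xv, d[1] * d[2]))
  dim(y) <- c(1L, 1L, d[3], d[4])
  ag_op(y, list(x), function(g) {
    gv <- as.vector(g) / (d[1] * d[2])
    list(array(rep(gv, each = d[1] * d[2]), d))
  })
}

ag_global_maxpool <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  m <- matrix(xv, d[1] * d[2])
  idx <- apply(m, 2L, which.max)
  y <- m[cbind(idx, seq_len(ncol(m)))]
  dim(y) <- c(1L, 1L, d[3], d[4])
  ag_op(y, list(x), function(g) {
    dm <- matrix(0, nrow(m), ncol(m))
    dm[cbind(idx, seq_len(ncol(m)))] <- as.vector(g)
    dim(dm) <- d
    list(dm)
  })
}

## mean over the channel axis -> (H, W, 1, N)
ag_channel_mean <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  S <- kronecker(diag(d[4]), rep(1, d[3]))
  y <- matrix(xv, d[1] * d[2]) %*% S / d[3]
  dim(y) <- c(d[1], d[2], 1L, d[4])
  ag_op(y, list(x), function(g) {
    list(expand_spatial(array(g, c(d[1], d[2], 1L, d[4])), d[3]) / d[3])
  })
}

## max over the channel axis -> (H, W, 1, N)
ag_channel_max <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  a <- array(xv, c(d[1] * d[2], d[3], d[4]))
  best <- a[, 1L, , drop = FALSE]
  arg <- array(1L, c(d[1] * d[2], 1L, d[4]))
  if (d[3] > 1L) for (c in 2:d[3]) {
    cur <- a[, c, , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    arg[upd] <- c
  }
  y <- array(best, c(d[1], d[2], 1L, d[4]))
  ag_op(y, list(x), function(g) {
    dg <- array(0, c(d[1] * d[2], d[3], d[4]))
    gv <- array(g, c(d[1] * d[2], 1L, d[4]))
    for (c in seq_len(d[3])) {
      sel <- arg == c
      tmp <- dg[, c, , drop = FALSE]
      tmp[sel] <- gv[sel]
      dg[, c, ] <- tmp
    }
    list(array(dg, d))
  })
}

## forward differences along width / height (result one shorter on that axis)
ag_diff_w <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  y <- xv[, -1L, , , drop = FALSE] - xv[, -d[2], , , drop = FALSE]
  ag_op(y, list(x), function(g) {
    dim(g) <- c(d[1], d[2] - 1L, d[3], d[4])
    dx <- array(0, d)
    dx[, -1L, , ] <- dx[, -1L, , , drop = FALSE] + g
    dx[, -d[2], , ] <- dx[, -d[2], , , drop = FALSE] - g
    list(dx)
  })
}

ag_diff_h <- function(x) {
  xv <- ag_value(x)
  d <- dim4(xv)
  y <- xv[-1L, , , , drop = FALSE] - xv[-d[1], , , , drop = FALSE]
  ag_op(y, list(x), function(g) {
    dim(g) <- c(d[1] - 1L, d[2], d[3], d[4])
    dx <- array(0, d)
    dx[-1L, , , ] <- dx[-1L, , , , drop = FALSE] + g
    dx[-d[1], , , ] <- dx[-d[1], , , , drop = FALSE] - g
    list(dx)
  })
}

## batch normalization over (H, W, N) per channel; `state` is an environment
## carrying running_mean / running_var for inference mode
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim4(xv)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  per_channel <- function(a) rowMeans(matrix(colMeans(matrix(a, d[1] * d[2])), C, d[4]))
  expand_c <- function(v) array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
  if (training) {
    mu <- per_channel(xv)
    va <- per_channel(xv * xv) - mu^2
    va[va < 0] <- 0
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xv - expand_c(mu)) * expand_c(istd)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  y <- xhat * expand_c(gv) + expand_c(bv)
  ag_op(y, list(x, gamma, beta), function(g) {
    dim(g) <- d
    dgamma_sum <- per_channel(g * xhat) * m
    dbeta_sum <- per_channel(g) * m
    dxhat <- g * expand_c(gv)
    if (training) {
      dx <- expand_c(istd) * (dxhat - expand_c(per_channel(dxhat)) -
                                xhat * expand_c(per_channel(dxhat * xhat)))
    } else {
      dx <- dxhat * expand_c(istd)
    }
    list(dx, dgamma_sum, dbeta_sum)
  })
}

## channel slice x[, , idx, ] keeping dims
ag_slice_c <- function(x, idx) {
  xv <- ag_value(x)
  d <- dim4(xv)
  y <- xv[, , idx, , drop = FALSE]
  ag_op(y, list(x), function(g) {
    dim(g) <- c(d[1], d[2], length(idx), d[4])
    dx <- array(0, d)
    dx[, , idx, ] <- g
    list(dx)
  })
}
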