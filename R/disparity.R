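## Self-supervised disparity estimation: a 7x7 stride-2 preprocessing
## convolution with batch normalization, an encoder of hierarchical split
## blocks (HSB) inside residual wrappers, and a multi-scale decoder with 3x3
## stride-2 transposed convolutions emitting sigmoid-bounded left/right
## disparity at the last four scales.

#' Hierarchical split block configuration
#'
#' @param s number of channel groups (>= 2, default 5); clamped to the
#'   channel count for very narrow layers.
#' @param k group convolution kernel size (3).
#' @return object of class `hsb_config`.
#' @export
hsb_config <- function(s = 5L, k = 3L) {
  stopifnot(s >= 2L, k >= 1L, k %% 2L == 1L)
  structure(list(s = as.integer(s), k = as.integer(k)), class = "hsb_config")
}

## split `total` channels into s near-equal groups
split_sizes <- function(total, s) {
  base <- total %/% s
  sizes <- rep(base, s)
  rem <- total %% s
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

## per-group conv input widths along the split/carry chain.
## carry gets ceiling(c/2), emitted half floor(c/2); last group emitted whole.
hsb_chain <- function(sizes) {
  s <- length(sizes)
  ins <- integer(0)
  emits <- sizes[1]
  carry <- 0L
  if (s >= 2L) for (i in 2:s) {
    ci <- sizes[i] + carry
    ins <- c(ins, ci)
    if (i < s) {
      carry <- (ci + 1L) %/% 2L
      emits <- c(emits, ci %/% 2L)
    } else emits <- c(emits, ci)
  }
  list(ins = ins, emits = emits, total_out = sum(emits))
}

#' Initialize a hierarchical split block
#'
#' A 1x1 convolution maps the input to the block width, which is split into
#' `s` groups: group 1 passes through; each later group's convolution sees
#' its split concatenated with the carried half of the previous group's
#' output; conv outputs are halved into carry/emit (the last emitted
#' whole).  A trailing 1x1 convolution restores the designed width and the
#' whole block sits inside a residual connection (1x1 projection when the
#' widths differ).
#'
#' @param cin input channels.
#' @param cout designed output channels (also the internal block width).
#' @param cfg an [hsb_config()].
#' @return nested parameter list for [hsb_forward()].
#' @export
hsb_init <- function(cin, cout, cfg = hsb_config()) {
  s_eff <- max(2L, min(cfg$s, cout))
  sizes <- split_sizes(cout, s_eff)
  ch <- hsb_chain(sizes)
  convs <- lapply(ch$ins, function(ci) nn_conv_param(cfg$k, cfg$k, ci, ci))
  list(pre = nn_conv_param(1L, 1L, cin, cout),
       convs = convs,
       post = nn_conv_param(1L, 1L, ch$total_out, cout),
       proj = if (cin != cout) nn_conv_param(1L, 1L, cin, cout) else NULL,
       sizes = sizes, cfg = cfg)
}

hsb_forward_ag <- function(x, wts) {
  cfg <- wts$cfg
  p <- (cfg$k - 1L) %/% 2L
  h <- ag_relu(ag_conv2d(x, wts$pre$w, wts$pre$b))
  sizes <- wts$sizes
  s <- length(sizes)
  off <- cumsum(c(0L, sizes))
  outs <- list(ag_slice_c(h, (off[1] + 1L):off[2]))
  carry <- NULL
  for (i in 2:s) {
    xi <- ag_slice_c(h, (off[i] + 1L):off[i + 1L])
    inp <- if (is.null(carry)) xi else ag_concat_c(list(xi, carry))
    y <- ag_relu(ag_conv2d(inp, wts$convs[[i - 1L]]$w, wts$convs[[i - 1L]]$b, pad = p))
    ci <- dim(ag_value(y))[3]
    if (i < s) {
      keep <- (ci + 1L) %/% 2L
      carry <- ag_slice_c(y, seq_len(keep))
      if (keep < ci)
        outs[[length(outs) + 1L]] <- ag_slice_c(y, (keep + 1L):ci)
    } else outs[[length(outs) + 1L]] <- y
  }
  body <- ag_conv2d(ag_concat_c(outs), wts$post$w, wts$post$b)
  res <- if (is.null(wts$proj)) x else ag_conv2d(x, wts$proj$w, wts$proj$b)
  ag_relu(ag_add(body, res))
}

#' Run a hierarchical split block on a feature map
#'
#' @param f (H, W, C) feature map.
#' @param cfg an [hsb_config()] (must match the one used at init).
#' @param stage_weights parameters from [hsb_init()].
#' @return (H, W, C') output feature map (spatial shape preserved).
#' @export
hsb_forward <- function(f, cfg, stage_weights) {
  d <- dim(f)
  out <- ag_value(hsb_forward_ag(ag_tensor(array(f, c(d, 1L))), stage_weights))
  array(out, dim(out)[1:3])
}

#' Parameter economy of the hierarchical split block
#'
#' Counts the convolutional weights of an actually constructed block with
#' `C = s * w` channels and compares them to the standard-convolution count
#' `k^2 s^2 w^2`.
#'
#' @param k kernel size.
#' @param w channels per group.
#' @param s number of groups.
#' @return list with `p_hsb` (counted block weights, biases excluded) and
#'   `p_standard`.
#' @export
hsb_param_count <- function(k, w, s) {
  stopifnot(k >= 1, w >= 1, s >= 1)
  C <- as.integer(s * w)
  p_standard <- k^2 * s^2 * w^2
  wts <- hsb_init(C, C, hsb_config(s = max(2L, s), k = as.integer(k)))
  weight_elems <- function(p) length(ag_value(p$w))
  p_hsb <- weight_elems(wts$pre) + weight_elems(wts$post) +
    sum(vapply(wts$convs, weight_elems, numeric(1)))
  list(p_hsb = p_hsb, p_standard = p_standard)
}

#' Disparity network specification
#'
#' @param width_multiplier channel scale factor (1 = full width).
#' @param hsb an [hsb_config()].
#' @param max_disparity_fraction upper bound on emitted disparity as a
#'   fraction of the image width at each scale (sigmoid scaling); 0.3
#'   keeps warps valid, the usual bound in self-supervised stereo.
#' @return object of class `disp_net_spec`.
#' @export
disp_net_spec <- function(width_multiplier = 1, hsb = hsb_config(),
                          max_disparity_fraction = 0.3) {
  stopifnot(max_disparity_fraction > 0, max_disparity_fraction < 1)
  ch <- function(v) pmax(4L, as.integer(round(v * width_multiplier)))
  structure(list(
    encoder_channels = ch(c(16, 32, 64, 128, 256)),
    decoder_channels = ch(c(256, 128, 64, 32, 16)),
    disparity_scales = 4L,
    hsb = hsb,
    max_disparity_fraction = max_disparity_fraction,
    width_multiplier = width_multiplier
  ), class = "disp_net_spec")
}

bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(channels)
  e$running_var <- rep(1, channels)
  e
}

bn_params <- function(channels) {
  list(gamma = ag_tensor(rep(1, channels), requires_grad = TRUE),
       beta = ag_tensor(numeric(channels), requires_grad = TRUE),
       state = bn_state(channels))
}

#' Build (initialize) a disparity network
#'
#' @param spec a [disp_net_spec()].
#' @param seed RNG seed for weight initialization.
#' @return untrained object of class `disparity_net`.
#' @export
build_disp_net <- function(spec = disp_net_spec(), seed = 1L) {
  stopifnot(inherits(spec, "disp_net_spec"))
  with_seed(seed, {
    ec <- spec$encoder_channels
    dc <- spec$decoder_channels
    pre <- c(list(conv = nn_conv_param(7L, 7L, 3L, ec[1])), bn_params(ec[1]))
    stages <- vector("list", 4L)
    for (i in 1:4)
      stages[[i]] <- c(list(entry = nn_conv_param(3L, 3L, ec[i], ec[i + 1]),
                            hsb = hsb_init(ec[i + 1], ec[i + 1], spec$hsb)),
                       bn_params(ec[i + 1]))
    dec <- vector("list", 5L)
    prev <- ec[5]
    for (j in 1:5) {
      co <- dc[j]
      skip_c <- if (j <= 4L) ec[5L - j] else 0L
      head <- NULL
      if (j >= 2L) {
        head <- nn_conv_param(3L, 3L, co, 2L)
        ## start near zero disparity (sigmoid(-3) ~ 0.047) with a gentle
        ## slope, so the photometric search grows the disparity outward from
        ## the identity warp instead of jumping in from half the range
        head$w$value <- head$w$value * 0.1
        head$b$value <- rep(-3, 2L)
      }
      dec[[j]] <- list(up = nn_tconv_param(3L, 3L, prev, co),
                       conv = nn_conv_param(3L, 3L, co + skip_c, co),
                       head = head)
      prev <- co
    }
    structure(list(spec = spec, params = list(pre = pre, stages = stages, dec = dec),
                   trained = FALSE, history = NULL, cfg = NULL, weights = NULL),
              class = "disparity_net")
  })
}

## forward pass on an (H, W, 3, N) batch (H, W divisible by 32).
## Returns list of 4 scales, finest last: each list(dl, dr, factor).
forward_disp <- function(net, x, training = TRUE) {
  spec <- net$spec
  p <- net$params
  h <- if (is_ag(x)) x else ag_tensor(x)
  W_full <- dim(ag_value(h))[2]
  h <- ag_conv2d(h, p$pre$conv$w, p$pre$conv$b, stride = 2L, pad = 3L)
  h <- ag_relu(ag_batchnorm(h, p$pre$gamma, p$pre$beta, p$pre$state, training))
  feats <- list(h)
  for (i in 1:4) {
    st <- p$stages[[i]]
    h <- ag_conv2d(h, st$entry$w, st$entry$b, stride = 2L, pad = 1L)
    h <- ag_relu(ag_batchnorm(h, st$gamma, st$beta, st$state, training))
    h <- hsb_forward_ag(h, st$hsb)
    feats[[i + 1L]] <- h
  }
  outs <- list()
  for (j in 1:5) {
    g <- p$dec[[j]]
    h <- ag_relu(ag_tconv2d(h, g$up$w, g$up$b, stride = 2L, pad = 1L, outpad = 1L))
    if (j <= 4L) h <- ag_concat_c(list(h, feats[[5L - j]]))
    h <- ag_relu(ag_conv2d(h, g$conv$w, g$conv$b, pad = 1L))
    if (!is.null(g$head)) {
      factor <- 2L^(5L - j)
      w_scale <- W_full / factor
      dd <- ag_smul(ag_sigmoid(ag_conv2d(h, g$head$w, g$head$b, pad = 1L)),
                    spec$max_disparity_fraction * w_scale)
      outs[[length(outs) + 1L]] <-
        list(dl = ag_slice_c(dd, 1L), dr = ag_slice_c(dd, 2L), factor = factor)
    }
  }
  outs
}

#' Predict a full-resolution left disparity map
#'
#' @param net a trained `disparity_net`.
#' @param left (H, W, 3) left image.  Sizes not divisible by 32 are resized
#'   internally and the disparity map (and its pixel values) rescaled back.
#' @return H x W nonnegative disparity matrix in pixels.
#' @export
predict_disparity <- function(net, left) {
  stopifnot(inherits(net, "disparity_net"))
  check_image(left)
  d0 <- dim(left)[1:2]
  h32 <- max(32L, as.integer(round(d0[1] / 32)) * 32L)
  w32 <- max(32L, as.integer(round(d0[2] / 32)) * 32L)
  x <- if (all(d0 == c(h32, w32))) left else resize_image(left, h32, w32)
  outs <- forward_disp(net, as_batch1(x), training = FALSE)
  fine <- outs[[length(outs)]]
  dl <- matrix(ag_value(fine$dl), h32, w32)
  if (!all(d0 == c(h32, w32))) {
    dl <- matrix(cpp_resize_bilinear(array(dl, c(h32, w32, 1L, 1L)), d0[1], d0[2]),
                 d0[1], d0[2])
    dl <- dl * d0[2] / w32
  }
  dl
}

## ---- training --------------------------------------------------------

resize_batch <- function(arr, h, w) cpp_resize_bilinear(arr, as.integer(h), as.integer(w))

## assemble cached per-sample constants into a batch (stack along N)
disp_batch_constants <- function(cached, idx) {
  lapply(seq_along(cached[[1]]), function(k) {
    sc <- cached[[idx[1]]][[k]]
    fields <- c("left", "right", "pe_id_l", "pe_id_r", "wx_l", "wy_l", "wx_r", "wy_r")
    out <- list(factor = sc$factor)
    for (f in fields) {
      pieces <- lapply(idx, function(i) cached[[i]][[k]][[f]])
      d <- dim(pieces[[1]])
      arr <- array(0, c(d[1], d[2], d[3], length(pieces)))
      for (q in seq_along(pieces)) arr[, , , q] <- pieces[[q]]
      out[[f]] <- arr
    }
    out
  })
}

## precompute per-scale constants for a batch of stereo pairs
disp_loss_constants <- function(left, right, w) {
  scales <- c(8L, 4L, 2L, 1L)
  lapply(scales, function(f) {
    d <- dim(left)
    hs <- d[1] %/% f; ws <- d[2] %/% f
    ls <- if (f == 1L) left else resize_batch(left, hs, ws)
    rs <- if (f == 1L) right else resize_batch(right, hs, ws)
    ## identity (unwarped) reprojection error, for auto-masking
    pe_id_l <- ag_value(photometric_ag(ls, rs, w))
    pe_id_r <- ag_value(photometric_ag(rs, ls, w))
    cm_grad <- function(img, axis) {
      gi <- if (axis == "w") abs(img[, -1, , , drop = FALSE] - img[, -ws, , , drop = FALSE])
            else abs(img[-1, , , , drop = FALSE] - img[-hs, , , , drop = FALSE])
      dd <- dim(gi)
      m <- matrix(gi, dd[1] * dd[2], dd[3] * dd[4]) %*%
        kronecker(diag(dd[4]), rep(1, dd[3])) / dd[3]
      array(exp(-m), c(dd[1], dd[2], 1L, dd[4]))
    }
    list(factor = f, left = ls, right = rs, pe_id_l = pe_id_l, pe_id_r = pe_id_r,
         wx_l = cm_grad(ls, "w"), wy_l = cm_grad(ls, "h"),
         wx_r = cm_grad(rs, "w"), wy_r = cm_grad(rs, "h"))
  })
}

## per-scale self-supervised loss (ag scalar) + diagnostic terms
disp_scale_loss <- function(sc, dl, dr, w) {
  recon_l <- ag_warp_h(sc$right, dl, -1)
  recon_r <- ag_warp_h(sc$left, dr, 1)
  pe_l <- photometric_ag(sc$left, recon_l, w)
  pe_r <- photometric_ag(sc$right, recon_r, w)
  if (w$automask_enabled) {
    mu_l <- (ag_value(pe_l) < sc$pe_id_l) * 1
    mu_r <- (ag_value(pe_r) < sc$pe_id_r) * 1
    ph_l <- ag_mean(ag_smul(pe_l, mu_l))
    ph_r <- ag_mean(ag_smul(pe_r, mu_r))
  } else {
    ph_l <- ag_mean(pe_l)
    ph_r <- ag_mean(pe_r)
  }
  lr_l <- ag_mean(ag_abs(ag_sub(dl, ag_warp_h(dr, dl, -1))))
  lr_r <- ag_mean(ag_abs(ag_sub(dr, ag_warp_h(dl, dr, 1))))
  ds_l <- ag_add(ag_mean(ag_smul(ag_abs(ag_diff_w(dl)), sc$wx_l)),
                 ag_mean(ag_smul(ag_abs(ag_diff_h(dl)), sc$wy_l)))
  ds_r <- ag_add(ag_mean(ag_smul(ag_abs(ag_diff_w(dr)), sc$wx_r)),
                 ag_mean(ag_smul(ag_abs(ag_diff_h(dr)), sc$wy_r)))
  reg <- ag_smul(ag_add(ag_add(lr_l, lr_r), ag_add(ds_l, ds_r)), w$lambda)
  ag_add(ag_add(ph_l, ph_r), reg)
}

#' Train the disparity network (self-supervised)
#'
#' Minimizes the per-scale combination of masked photometric reprojection
#' error (both eyes), left-right disparity consistency and edge-aware
#' smoothness, averaged over the four emitted scales, with Adam.
#'
#' @param samples list of `stereo_sample` objects (only `left`/`right` are
#'   used; no ground truth enters training).
#' @param spec a [disp_net_spec()].
#' @param cfg a [train_config()] (its `input_size` must be divisible by 32).
#' @param weights a [loss_weights()].
#' @param verbose print per-epoch losses?
#' @return a trained `disparity_net` with `$history`.
#' @export
train_disparity <- function(samples, spec = disp_net_spec(),
                            cfg = train_config(), weights = loss_weights(),
                            verbose = FALSE) {
  stopifnot(length(samples) >= 1L, all(cfg$input_size %% 32L == 0L))
  net <- build_disp_net(spec, seed = cfg$seed)
  net$cfg <- cfg
  net$weights <- weights
  hs <- cfg$input_size
  prep <- function(im) if (all(dim(im)[1:2] == hs)) im else resize_image(im, hs[1], hs[2])
  lefts <- lapply(samples, function(s) prep(s$left))
  rights <- lapply(samples, function(s) prep(s$right))
  ## per-sample loss constants (image pyramids, identity reprojection
  ## errors, edge weights) are fixed across epochs: compute them once
  cached <- lapply(seq_along(lefts), function(i)
    disp_loss_constants(as_batch1(lefts[[i]]), as_batch1(rights[[i]]), weights))
  params <- nn_collect_params(net$params)
  opt <- adam_init(params, lr = cfg$learning_rate)
  history <- numeric(0)
  if (cfg$epochs > 0L) with_seed(cfg$seed + 1L, {
    n <- length(lefts)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        lb <- stack_images(lefts[idx])
        consts <- disp_batch_constants(cached, idx)
        ag_zero_grad(params)
        outs <- forward_disp(net, ag_tensor(lb), training = TRUE)
        terms <- lapply(seq_along(outs), function(k)
          disp_scale_loss(consts[[k]], outs[[k]]$dl, outs[[k]]$dr, weights))
        loss <- ag_smul(Reduce(ag_add, terms), 1 / length(terms))
        if (!is.finite(loss$value)) stop("training diverged (non-finite loss)")
        ag_backward(loss)
        opt <- adam_step(opt)
        ep_loss <- ep_loss + loss$value
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs, history[ep]))
    }
  })
  net$trained <- cfg$epochs > 0L
  net$history <- history
  net
}

#' @export
predict.disparity_net <- function(object, newdata, ...) predict_disparity(object, newdata)

#' @export
print.disparity_net <- function(x, ...) {
  cat("Self-supervised disparity network (HSB encoder, 4-scale decoder)\n")
  cat("  width multiplier:", x$spec$width_multiplier,
      " groups s:", x$spec$hsb$s,
      " parameters:", nn_param_count(x$params), "\n")
  if (x$trained)
    cat("  trained", length(x$history), "epochs; final loss:",
        signif(utils::tail(x$history, 1), 4), "\n")
  else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.disparity_net <- function(object, ...) {
  c(parameters = nn_param_count(object$params))
}

#' @export
plot.disparity_net <- function(x, ...) {
  if (!length(x$history)) stop("no training history to plot")
  graphics::plot(seq_along(x$history), x$history, type = "b",
                 xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}
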