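## Desmoking U-Net: seven-scale encoder with Laplacian-pyramid fusion
## injection, seven-scale decoder with CBAM refinement in five groups, skip
## connections, sigmoid RGB head, L1 reconstruction loss.

#' Desmoking network specification
#'
#' Seven encoder groups (kernels 7,5,3,3,3,3,3; two convolutions per group
#' with strides 1 and 2, the last group stride 1 so the total down-sampling
#' factor is 64) and seven decoder groups (kernel 3).  All channel widths
#' scale by a single `width_multiplier` so desk-scale configurations share
#' the full topology.
#'
#' @param width_multiplier channel scale factor (1 = full width; 1/8 for
#'   desk-scale training).
#' @param laplacian_injection concatenate the per-scale Laplacian fusion
#'   image (3 channels) to each encoder group's input?
#' @param cbam_position `"last5"` (default) or `"first5"`: which five
#'   decoder groups carry a CBAM block.
#' @param reduction_ratio CBAM channel-bottleneck ratio.
#' @return object of class `desmoke_net_spec`.
#' @export
desmoke_net_spec <- function(width_multiplier = 1, laplacian_injection = TRUE,
                             cbam_position = c("last5", "first5"),
                             reduction_ratio = 16L) {
  cbam_position <- match.arg(cbam_position)
  ch <- function(v) pmax(4L, as.integer(round(v * width_multiplier)))
  structure(list(
    encoder_kernels = c(7L, 5L, 3L, 3L, 3L, 3L, 3L),
    encoder_channels = ch(c(32, 64, 128, 256, 512, 512, 512)),
    encoder_strides = c(2L, 2L, 2L, 2L, 2L, 2L, 1L),
    decoder_channels = ch(c(512, 512, 256, 128, 64, 32, 16)),
    decoder_kernel = 3L,
    cbam_layers = if (cbam_position == "last5") 3:7 else 1:5,
    laplacian_injection = isTRUE(laplacian_injection),
    reduction_ratio = as.integer(reduction_ratio),
    width_multiplier = width_multiplier
  ), class = "desmoke_net_spec")
}

#' Training configuration
#'
#' @param input_size `c(H, W)` all frames are resized to before training.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training pairs.
#' @param seed RNG seed (weight init + shuffling).
#' @return object of class `train_config`.
#' @export
train_config <- function(input_size = c(128L, 256L), learning_rate = 1e-4,
                         batch_size = 16L, epochs = 20L, seed = 1L) {
  stopifnot(all(input_size > 0), learning_rate > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(input_size = as.integer(input_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

## spatial sizes entering each encoder group for an input of (H, W)
desmoke_encoder_scales <- function(spec, input_size) {
  h <- input_size[1]; w <- input_size[2]
  scales <- vector("list", 7L)
  for (i in 1:7) {
    scales[[i]] <- c(h, w)
    s <- spec$encoder_strides[i]
    if (s == 2L) { h <- (h + 1L) %/% 2L; w <- (w + 1L) %/% 2L }
  }
  scales
}

#' Build (initialize) a desmoking network
#'
#' @param spec a [desmoke_net_spec()].
#' @param seed RNG seed for weight initialization.
#' @return untrained object of class `desmoke_net`.
#' @export
build_desmoke_net <- function(spec = desmoke_net_spec(), seed = 1L) {
  stopifnot(inherits(spec, "desmoke_net_spec"))
  with_seed(seed, {
    inj <- if (spec$laplacian_injection) 3L else 0L
    enc <- vector("list", 7L)
    cin <- 3L
    for (i in 1:7) {
      k <- spec$encoder_kernels[i]
      co <- spec$encoder_channels[i]
      enc[[i]] <- list(
        c1 = nn_conv_param(k, k, cin + inj, co),
        c2 = nn_conv_param(k, k, co, co))
      cin <- co
    }
    ## decoder group j consumes the previous decoder feature (or the encoder
    ## top) plus a skip: groups 1..6 take encoder outputs 6..1; group 7 takes
    ## the input image itself.
    dec <- vector("list", 7L)
    prev <- spec$encoder_channels[7L]
    for (j in 1:7) {
      co <- spec$decoder_channels[j]
      skip_c <- if (j <= 6L) spec$encoder_channels[7L - j] else 3L
      dec[[j]] <- list(
        c1 = nn_conv_param(3L, 3L, prev + skip_c, co),
        c2 = nn_conv_param(3L, 3L, co, co),
        cbam = if (j %in% spec$cbam_layers)
          cbam_init(co, cbam_config(spec$reduction_ratio)) else NULL)
      prev <- co
    }
    head <- nn_conv_param(1L, 1L, prev, 3L)
    structure(list(spec = spec, params = list(enc = enc, dec = dec, head = head),
                   trained = FALSE, history = NULL, cfg = NULL),
              class = "desmoke_net")
  })
}

## fusion stack for a batch: list over 7 scales of (h, w, 3, N) arrays
desmoke_fusion_batch <- function(imgs, scales) {
  stacks <- lapply(imgs, function(im) fusion_stack(im, scales))
  lapply(1:7, function(i) stack_images(lapply(stacks, `[[`, i)))
}

## forward pass on an (H, W, 3, N) batch; fusion is a list of 7 batches or
## NULL (computed from the input frames)
forward_desmoke <- function(net, x, fusion = NULL) {
  spec <- net$spec
  d <- dim(ag_value(x))
  if (is.null(fusion) && spec$laplacian_injection) {
    scales <- desmoke_encoder_scales(spec, d[1:2])
    fusion <- desmoke_fusion_batch(unstack_images(ag_value(x)), scales)
  }
  skips <- vector("list", 7L)
  h <- if (is_ag(x)) x else ag_tensor(x)
  input_img <- h
  for (i in 1:7) {
    if (spec$laplacian_injection) h <- ag_concat_c(list(h, ag_tensor(fusion[[i]])))
    k <- spec$encoder_kernels[i]
    p <- (k - 1L) %/% 2L
    g <- net$params$enc[[i]]
    h <- ag_relu(ag_conv2d(h, g$c1$w, g$c1$b, stride = 1L, pad = p))
    h <- ag_relu(ag_conv2d(h, g$c2$w, g$c2$b, stride = spec$encoder_strides[i], pad = p))
    skips[[i]] <- h
  }
  for (j in 1:7) {
    g <- net$params$dec[[j]]
    skip <- if (j <= 6L) skips[[7L - j]] else input_img
    ds <- dim(ag_value(skip))
    dh <- dim(ag_value(h))
    if (dh[1] != ds[1] || dh[2] != ds[2]) h <- ag_upsample(h, ds[1], ds[2])
    h <- ag_concat_c(list(h, skip))
    h <- ag_relu(ag_conv2d(h, g$c1$w, g$c1$b, pad = 1L))
    h <- ag_relu(ag_conv2d(h, g$c2$w, g$c2$b, pad = 1L))
    if (!is.null(g$cbam)) h <- cbam_ag(h, g$cbam)
  }
  ag_sigmoid(ag_conv2d(h, net$params$head$w, net$params$head$b))
}

#' L1 reconstruction loss between clean and desmoked frames
#'
#' Sum of absolute per-pixel, per-channel deviations, reported both as the
#' raw sum and as the per-entry mean.
#'
#' @param original,desmoked (H, W, 3) images of equal shape.
#' @return list with `sum` and `mean`.
#' @export
desmoke_loss <- function(original, desmoked) {
  if (!all(dim(original) == dim(desmoked)))
    stop("image shapes must match", call. = FALSE)
  s <- sum(abs(original - desmoked))
  list(sum = s, mean = s / length(original))
}

#' Train the desmoking network
#'
#' Adam on the per-pixel L1 loss between the network output for a fogged
#' frame and its clean label.  Deterministic for a fixed seed.
#'
#' @param pairs list of `list(fogged, clean)` image pairs (from
#'   [fog_dataset()]).
#' @param spec a [desmoke_net_spec()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses?
#' @return a trained `desmoke_net` with `$history` (per-epoch mean L1).
#' @export
train_desmoke <- function(pairs, spec = desmoke_net_spec(),
                          cfg = train_config(), verbose = FALSE) {
  stopifnot(length(pairs) >= 1L)
  net <- build_desmoke_net(spec, seed = cfg$seed)
  net$cfg <- cfg
  hs <- cfg$input_size
  prep <- function(im) if (all(dim(im)[1:2] == hs)) im else resize_image(im, hs[1], hs[2])
  fogged <- lapply(pairs, function(p) prep(p$fogged))
  clean <- lapply(pairs, function(p) prep(p$clean))
  scales <- desmoke_encoder_scales(spec, hs)
  fus <- if (spec$laplacian_injection)
    lapply(fogged, function(im) fusion_stack(im, scales)) else NULL
  params <- nn_collect_params(net$params)
  opt <- adam_init(params, lr = cfg$learning_rate)
  history <- numeric(0)
  if (cfg$epochs > 0L) with_seed(cfg$seed + 1L, {
    n <- length(fogged)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        xb <- stack_images(fogged[idx])
        yb <- stack_images(clean[idx])
        fb <- if (!is.null(fus))
          lapply(1:7, function(i) stack_images(lapply(fus[idx], `[[`, i))) else NULL
        ag_zero_grad(params)
        out <- forward_desmoke(net, ag_tensor(xb), fusion = fb)
        loss <- ag_mean(ag_abs(ag_sub(out, ag_tensor(yb))))
        if (!is.finite(loss$value)) stop("training diverged (non-finite loss)")
        ag_backward(loss)
        opt <- adam_step(opt)
        ep_loss <- ep_loss + loss$value
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  mean L1 %.5f", ep, cfg$epochs, history[ep]))
    }
  })
  net$trained <- cfg$epochs > 0L
  net$history <- history
  net
}

#' Remove smoke from a frame with a trained network
#'
#' The frame is resized to the network's training size if needed, passed
#' through the network, and resized back; output is clipped to `[0, 1]`.
#'
#' @param net a trained `desmoke_net`.
#' @param fogged (H, W, 3) image.
#' @return desmoked (H, W, 3) image.
#' @export
desmoke <- function(net, fogged) {
  stopifnot(inherits(net, "desmoke_net"))
  check_image(fogged)
  d0 <- dim(fogged)[1:2]
  hs <- if (!is.null(net$cfg)) net$cfg$input_size else d0
  x <- if (all(d0 == hs)) fogged else resize_image(fogged, hs[1], hs[2])
  out <- from_batch1(ag_value(forward_desmoke(net, ag_tensor(as_batch1(x)))))
  out <- clip01(out)
  if (!all(d0 == hs)) out <- resize_image(out, d0[1], d0[2])
  out
}

#' @export
predict.desmoke_net <- function(object, newdata, ...) desmoke(object, newdata)

#' @export
print.desmoke_net <- function(x, ...) {
  cat("Desmoking U-Net (7-scale encoder/decoder, Laplacian fusion",
      if (x$spec$laplacian_injection) "on," else "off,",
      "CBAM groups:", paste(x$spec$cbam_layers, collapse = ","), ")\n")
  cat("  width multiplier:", x$spec$width_multiplier,
      " parameters:", nn_param_count(x$params), "\n")
  if (x$trained)
    cat("  trained", length(x$history), "epochs; final mean L1:",
        signif(utils::tail(x$history, 1), 4), "\n")
  else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.desmoke_net <- function(object, ...) {
  c(parameters = nn_param_count(object$params))
}

#' @export
plot.desmoke_net <- function(x, ...) {
  if (!length(x$history)) stop("no training history to plot")
  graphics::plot(seq_along(x$history), x$history, type = "b",
                 xlab = "epoch", ylab = "mean L1 loss", ...)
  invisible(x)
}
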