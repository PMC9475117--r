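## Convolutional Block Attention Module: sequential channel attention
## (shared two-layer MLP over globally average- and max-pooled channel
## vectors, summed, sigmoid) and spatial attention (7x7 convolution over the
## channel-wise mean and max maps, sigmoid), each multiplied into the
## features.  Feature maps on the public surface are (H, W, C) arrays.

#' CBAM configuration
#'
#' @param reduction_ratio bottleneck ratio `r` of the channel MLP (default
#'   16, the module's published default); clamped to the channel count when
#'   `C < r`.
#' @param spatial_kernel spatial-attention kernel size (7).
#' @return object of class `cbam_config`.
#' @export
cbam_config <- function(reduction_ratio = 16L, spatial_kernel = 7L) {
  stopifnot(reduction_ratio >= 1L, spatial_kernel %% 2L == 1L)
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "cbam_config")
}

#' Initialize CBAM weights for a given channel count
#'
#' @param channels number of input channels `C`.
#' @param cfg a [cbam_config()].
#' @return nested list of `ag_tensor` parameters (`mlp1`, `mlp2` 1x1 convs;
#'   `spatial` k x k conv over the 2-channel pooled map).
#' @export
cbam_init <- function(channels, cfg = cbam_config()) {
  r <- min(cfg$reduction_ratio, channels)
  hidden <- max(1L, channels %/% r)
  k <- cfg$spatial_kernel
  list(mlp1 = nn_conv_param(1L, 1L, channels, hidden),
       mlp2 = nn_conv_param(1L, 1L, hidden, channels),
       spatial = nn_conv_param(k, k, 2L, 1L),
       cfg = cfg)
}

## autograd forward passes ----------------------------------------------

cbam_channel_ag <- function(x, wts) {
  mlp <- function(v) ag_conv2d(ag_relu(ag_conv2d(v, wts$mlp1$w, wts$mlp1$b)),
                               wts$mlp2$w, wts$mlp2$b)
  ag_sigmoid(ag_add(mlp(ag_global_avgpool(x)), mlp(ag_global_maxpool(x))))
}

cbam_spatial_ag <- function(x, wts) {
  pooled <- ag_concat_c(list(ag_channel_mean(x), ag_channel_max(x)))
  k <- dim(ag_value(wts$spatial$w))[1]
  ag_sigmoid(ag_conv2d(pooled, wts$spatial$w, wts$spatial$b, pad = (k - 1L) %/% 2L))
}

cbam_ag <- function(x, wts) {
  fp <- ag_scale_channels(x, cbam_channel_ag(x, wts))
  ag_scale_spatial(fp, cbam_spatial_ag(fp, wts))
}

## public array-level surface -------------------------------------------

as_feature_batch <- function(f) {
  d <- dim(f)
  stopifnot(length(d) == 3L)
  array(f, c(d, 1L))
}

#' Channel attention weights
#'
#' Global average- and max-pooled channel vectors pass through a shared
#' bottleneck MLP (ReLU after the first layer), are summed and squashed by
#' a sigmoid, giving one weight per channel in `(0, 1)`.
#'
#' @param f (H, W, C) feature map.
#' @param wts weights from [cbam_init()].
#' @return length-`C` vector of weights, all strictly in `(0, 1)`.
#' @export
channel_attention <- function(f, wts) {
  as.vector(ag_value(cbam_channel_ag(ag_tensor(as_feature_batch(f)), wts)))
}

#' Spatial attention map
#'
#' Channel-wise mean and max maps are stacked (2 channels) and convolved
#' with a single 7x7 kernel, then sigmoid-squashed.
#'
#' @inheritParams channel_attention
#' @return H x W matrix of weights in `(0, 1)`.
#' @export
spatial_attention <- function(f, wts) {
  d <- dim(f)
  matrix(ag_value(cbam_spatial_ag(ag_tensor(as_feature_batch(f)), wts)), d[1], d[2])
}

#' Apply the full CBAM refinement
#'
#' `F'' = Ms(Mc(F) * F) * (Mc(F) * F)`: channel attention first, then
#' spatial attention on the channel-refined features, both as broadcast
#' elementwise products.
#'
#' @inheritParams channel_attention
#' @return refined (H, W, C) feature map.
#' @export
cbam <- function(f, wts) {
  d <- dim(f)
  array(ag_value(cbam_ag(ag_tensor(as_feature_batch(f)), wts)), d)
}
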