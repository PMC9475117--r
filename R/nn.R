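## Parameter containers, initialization and the Adam optimizer.

## He (Kaiming) normal initialization for a conv weight of dim
## (kh, kw, Cin, Cout); fan-in = kh*kw*Cin.
nn_conv_param <- function(kh, kw, cin, cout, gain = 2) {
  sd <- sqrt(gain / (kh * kw * cin))
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  list(w = ag_tensor(w, requires_grad = TRUE),
       b = ag_tensor(numeric(cout), requires_grad = TRUE))
}

## transposed-conv weight: dim (kh, kw, Cout, Cin), fan-in = kh*kw*Cin / stride^2
nn_tconv_param <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  w <- array(stats::rnorm(kh * kw * cout * cin, sd = sd), c(kh, kw, cout, cin))
  list(w = ag_tensor(w, requires_grad = TRUE),
       b = ag_tensor(numeric(cout), requires_grad = TRUE))
}

## flatten a nested list of {w,b} param pairs into a flat list of ag tensors
nn_collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is_ag(e)) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

nn_param_count <- function(params) {
  sum(vapply(nn_collect_params(params), function(p) length(p$value), numeric(1)))
}

#' Adam optimizer state
#'
#' @param params flat list of `ag_tensor` parameters.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @keywords internal
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) 0 * p$value),
       v = lapply(params, function(p) 0 * p$value),
       t = 0L)
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g * g
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

## stack a list of (H,W,C) arrays into an (H,W,C,N) batch
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (k in seq_along(imgs)) out[, , , k] <- imgs[[k]]
  out
}

## split an (H,W,C,N) batch back into a list of (H,W,C) arrays
unstack_images <- function(batch) {
  d <- dim(batch)
  lapply(seq_len(d[4]), function(k) array(batch[, , , k], d[1:3]))
}
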