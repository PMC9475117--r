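## Minimal reverse-mode automatic differentiation on dense 4-d arrays.
##
## Tensors hold values with dim (H, W, C, N) (or a length-1 scalar for
## losses).  Every operation records its parents and a closure computing the
## vector-Jacobian product; ag_backward() replays the tape in reverse
## creation order.  This is deliberately small: just enough machinery for the
## convolutional encoder/decoder networks and loss stack in this package.

.ag_state <- new.env(parent = emptyenv())
.ag_state$id <- 0L

#' Create an autograd tensor
#'
#' Wraps a numeric array (dim `(H, W, C, N)`) or scalar as a node of the
#' reverse-mode differentiation tape used by the network trainers.
#'
#' @param value numeric array or scalar.
#' @param requires_grad should gradients be accumulated into this node?
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires <- isTRUE(requires_grad)
  t$parents <- list()
  t$bwd <- NULL
  .ag_state$id <- .ag_state$id + 1L
  t$id <- .ag_state$id
  class(t) <- "ag_tensor"
  t
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_ag(x)) x$value else x

## Internal constructor for op results.  `bwd` takes the upstream gradient
## and returns a list of gradients aligned with `parents` (NULL = no grad).
ag_op <- function(value, parents, bwd) {
  need <- vapply(parents, function(p) is_ag(p) && p$requires, logical(1))
  out <- ag_tensor(value, requires_grad = any(need))
  if (any(need)) {
    out$parents <- parents
    out$bwd <- bwd
  }
  out
}

#' Run backpropagation from a scalar loss
#'
#' @param root an `ag_tensor` holding a scalar value.
#' @keywords internal
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$value) == 1L)
  ## collect reachable nodes
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- nd
    for (p in nd$parents) if (is_ag(p)) stack[[length(stack) + 1L]] <- p
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  root$grad <- 1
  for (id in ids) {
    nd <- nodes[[as.character(id)]]
    if (is.null(nd$bwd) || is.null(nd$grad)) next
    grads <- nd$bwd(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!is_ag(p) || !p$requires) next
      g <- grads[[k]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

#' Drop accumulated gradients on a list of parameters
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## detach: value as plain array (stops gradient flow)
ag_detach <- function(x) ag_value(x)
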