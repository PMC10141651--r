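## Reverse-mode automatic differentiation on a linear tape.
##
## Tensors are dense R arrays with dims (H, W, C, N); every op records the
## value and a backward closure on the tape, and tape_backward() replays the
## tape in reverse, accumulating gradients into node$grad.  Learnable
## parameters are environments (hf_param); a parameter appearing several
## times on one tape (shared encoders, residual reuse) maps to a single leaf
## node so its gradients from all uses accumulate automatically.

.hf_counter <- new.env(parent = emptyenv())
.hf_counter$n <- 0L

next_param_id <- function() {
  .hf_counter$n <- .hf_counter$n + 1L
  .hf_counter$n
}

#' Create a learnable parameter
#'
#' @param value initial numeric array/matrix/vector.
#' @param name label used in diagnostics and checkpoints.
#' @return an environment of class `hf_param` with fields `value` and `grad`.
#' @keywords internal
new_param <- function(value, name = "param") {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$m <- NULL   # Adam first moment
  e$v <- NULL   # Adam second moment
  e$name <- name
  e$id <- next_param_id()
  class(e) <- "hf_param"
  e
}

#' Start a fresh autodiff tape
#'
#' @param train logical; training mode enables dropout and batch statistics
#'   in batch normalisation.
#' @param grad logical; FALSE skips gradient bookkeeping (and the saved
#'   activations that back it) for inference-only forwards.
#' @keywords internal
new_tape <- function(train = TRUE, grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$train <- isTRUE(train)
  tp$grad <- isTRUE(grad)
  tp$leaves <- new.env(parent = emptyenv())  # param id -> list(node, param)
  class(tp) <- "hf_tape"
  tp
}

tp_push <- function(tp, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tp$n + 1L
  if (n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

## Leaf for an input tensor (gradient retrievable but not a parameter).
op_input <- function(tp, x) tp_push(tp, x)

## Leaf for a parameter; memoised per tape so shared use accumulates.
tp_leaf <- function(tp, param) {
  key <- as.character(param$id)
  hit <- tp$leaves[[key]]
  if (!is.null(hit)) return(hit$node)
  nd <- tp_push(tp, param$value)
  tp$leaves[[key]] <- list(node = nd, param = param)
  nd
}

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#'
#' Accumulates gradients along the tape and copies leaf gradients into their
#' parameters' `grad` fields (added to any existing gradient).
#' @keywords internal
tape_backward <- function(tp, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  for (key in ls(tp$leaves)) {
    lf <- tp$leaves[[key]]
    if (!is.null(lf$node$grad)) {
      p <- lf$param
      p$grad <- if (is.null(p$grad)) lf$node$grad else p$grad + lf$node$grad
    }
  }
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

op_relu <- function(tp, x) {
  out <- relu_fwd_cpp(x$value)
  tp_push(tp, out, backward = function(g) acc_grad(x, relu_bwd_cpp(g, out)))
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$value))
  tp_push(tp, s, backward = function(g) acc_grad(x, g * s * (1 - s)))
}

op_add <- function(tp, x, y) {
  tp_push(tp, x$value + y$value, backward = function(g) {
    acc_grad(x, g); acc_grad(y, g)
  })
}

op_mul <- function(tp, x, y) {
  xv <- x$value; yv <- y$value
  tp_push(tp, xv * yv, backward = function(g) {
    acc_grad(x, g * yv); acc_grad(y, g * xv)
  })
}

## Elementwise maximum of two tensors; ties route the gradient to `x`.
op_pmax2 <- function(tp, x, y) {
  mask <- x$value >= y$value
  tp_push(tp, pmax(x$value, y$value), backward = function(g) {
    acc_grad(x, g * mask); acc_grad(y, g * !mask)
  })
}

## Clamp with straight-through gradient inside the range.
op_clamp <- function(tp, x, lo, hi) {
  inside <- x$value >= lo & x$value <= hi
  tp_push(tp, pmin(pmax(x$value, lo), hi),
          backward = function(g) acc_grad(x, g * inside))
}

op_dropout <- function(tp, x, rate) {
  if (!tp$train || rate <= 0) return(x)
  fw <- dropout_fwd_cpp(x$value, rate)
  tp_push(tp, fw$out,
          backward = function(g) acc_grad(x, dropout_bwd_cpp(g, fw$mask, rate)))
}

## Hybrid fusion of n same-shaped maps -> 3C channels (sum/product/max).
## Reductions run in elementwise-sorted order, so the value is bit-identical
## under permutation of the inputs.
op_fuse <- function(tp, xs, clip = 1e6) {
  vals <- lapply(xs, `[[`, "value")
  out <- fuse_fwd_cpp(vals, clip)
  tp_push(tp, out, backward = function(g) {
    gs <- fuse_bwd_cpp(g, vals, clip)
    for (j in seq_along(xs)) acc_grad(xs[[j]], gs[[j]])
  })
}

## ---- structural ops --------------------------------------------------------

## Channel-wise concatenation of a list of (H,W,Ci,N) nodes.
op_concat_c <- function(tp, xs) {
  d1 <- dim(xs[[1]]$value)
  chans <- vapply(xs, function(x) dim(x$value)[3], integer(1))
  Cs <- sum(chans)
  out <- array(0, c(d1[1], d1[2], Cs, d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$value)[3]
    out[, , at + seq_len(cc), ] <- x$value
    at <- at + cc
  }
  tp_push(tp, out, backward = function(g) {
    at <- 0L
    for (x in xs) {
      cc <- dim(x$value)[3]
      acc_grad(x, g[, , at + seq_len(cc), , drop = FALSE])
      at <- at + cc
    }
  })
}

## Global average pooling (H,W,C,N) -> (1,1,C,N).
op_gap <- function(tp, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  mu <- colMeans(matrix(x$value, nrow = hw))
  tp_push(tp, array(mu, c(1, 1, d[3], d[4])), backward = function(g) {
    acc_grad(x, array(rep(as.vector(g), each = hw) / hw, d))
  })
}

## Broadcast (1,1,C,N) -> (H,W,C,N).
op_broadcast_hw <- function(tp, x, H, W) {
  d <- dim(x$value)
  hw <- H * W
  v <- array(rep(as.vector(x$value), each = hw), c(H, W, d[3], d[4]))
  tp_push(tp, v, backward = function(g) {
    acc_grad(x, array(colSums(matrix(g, nrow = hw)), d))
  })
}

## ---- compiled-kernel ops ---------------------------------------------------

op_conv2d <- function(tp, x, wp, bp = NULL, k = 3L, pad = NULL, stride = 1L,
                      dilation = 1L) {
  if (is.null(pad)) pad <- if (k == 1L) 0L else dilation * (k - 1L) %/% 2L
  wn <- tp_leaf(tp, wp)
  bn <- if (!is.null(bp)) tp_leaf(tp, bp)
  xd <- dim(x$value)
  if (ncol(wp$value) != k * k * xd[3])
    stop("conv2d '", wp$name, "': input has ", xd[3],
         " channels but weight expects ", ncol(wp$value) / (k * k))
  fw <- conv2d_fwd_cpp(x$value, wn$value,
                       if (is.null(bp)) numeric(0) else as.numeric(bn$value),
                       k, k, pad, stride, dilation, tp$grad)
  if (!tp$grad) return(tp_push(tp, fw$out))
  tp_push(tp, fw$out, backward = function(g) {
    r <- conv2d_bwd_cpp(g, fw$cols, wn$value, xd, k, k, pad, stride,
                        dilation, !is.null(bp))
    fw$cols <- NULL                   # patch matrix freed by the bwd kernel
    acc_grad(x, r$dx)
    acc_grad(wn, r$dW)
    if (!is.null(bp)) acc_grad(bn, r$db)
  })
}

op_tconv2 <- function(tp, x, wp, bp = NULL) {
  wn <- tp_leaf(tp, wp)
  bn <- if (!is.null(bp)) tp_leaf(tp, bp)
  xv <- x$value
  out <- tconv2_fwd_cpp(xv, wn$value,
                        if (is.null(bp)) numeric(0) else as.numeric(bn$value))
  tp_push(tp, out, backward = function(g) {
    r <- tconv2_bwd_cpp(g, xv, wn$value, !is.null(bp))
    acc_grad(x, r$dx)
    acc_grad(wn, r$dW)
    if (!is.null(bp)) acc_grad(bn, r$db)
  })
}

op_maxpool2 <- function(tp, x) {
  d <- dim(x$value)
  fw <- maxpool2_fwd_cpp(x$value)
  tp_push(tp, fw$out, backward = function(g) {
    acc_grad(x, maxpool2_bwd_cpp(g, fw$arg, d[1], d[2]))
  })
}

## ---- batch normalisation ---------------------------------------------------

op_batchnorm <- function(tp, x, gp, bp, state, eps = 1e-5, momentum = 0.1) {
  gn <- tp_leaf(tp, gp)
  bn <- tp_leaf(tp, bp)
  if (tp$train) {
    st <- bn_stats_cpp(x$value)
    mu <- st$mean
    va <- st$var
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  fw <- bn_fwd_cpp(x$value, gn$value, bn$value, mu, va, eps, tp$grad)
  if (!tp$grad) return(tp_push(tp, fw$out))
  sd_ <- sqrt(va + eps)
  train <- tp$train
  tp_push(tp, fw$out, backward = function(g) {
    r <- bn_bwd_cpp(g, fw$xhat, gn$value, sd_, train)
    fw$xhat <- NULL                   # freed by the bwd kernel
    acc_grad(gn, r$dgamma)
    acc_grad(bn, r$dbeta)
    acc_grad(x, r$dx)
  })
}

## ---- losses ----------------------------------------------------------------

## Channel-wise softmax over dim 3 of (H,W,C,N).
softmax4 <- function(v) {
  d <- dim(v)
  X <- matrix(aperm(v, c(1, 2, 4, 3)), ncol = d[3])   # pixels x classes
  X <- X - do.call(pmax, lapply(seq_len(d[3]), function(c) X[, c]))
  E <- exp(X)
  P <- E / rowSums(E)
  aperm(array(P, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

op_softmax <- function(tp, x) {
  p <- softmax4(x$value)
  d <- dim(p)
  tp_push(tp, p, backward = function(g) {
    gp <- g * p
    s <- array(0, d)
    tot <- apply(gp, c(1, 2, 4), sum)        # sum over classes per pixel
    for (c in seq_len(d[3])) s[, , c, ] <- tot
    acc_grad(x, gp - p * s)
  })
}

## Mean per-pixel cross entropy of integer labels (H,W,N) in 0..C-1.
op_cross_entropy <- function(tp, logits, labels) {
  d <- dim(logits$value)
  C <- d[3]
  npix <- d[1] * d[2] * d[4]
  X <- matrix(aperm(logits$value, c(1, 2, 4, 3)), ncol = C)
  mx <- do.call(pmax, lapply(seq_len(C), function(c) X[, c]))
  Z <- X - mx
  lse <- log(rowSums(exp(Z)))
  lab1 <- as.vector(labels) + 1L
  val <- -mean(Z[cbind(seq_len(npix), lab1)] - lse)
  tp_push(tp, val, backward = function(g) {
    P <- exp(Z - lse)
    P[cbind(seq_len(npix), lab1)] <- P[cbind(seq_len(npix), lab1)] - 1
    dX <- P * (g / npix)
    acc_grad(logits, aperm(array(dX, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

one_hot4 <- function(labels, C) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], C, d[3]))
  for (c in 0:(C - 1)) out[, , c + 1, ] <- labels == c
  out
}

## Soft Dice loss: 1 - mean over classes and batch of the per-class soft
## Dice coefficient, smoothed by `smooth` in numerator and denominator.
op_dice <- function(tp, probs, labels, smooth = 1e-5,
                    include_background = TRUE) {
  d <- dim(probs$value)
  C <- d[3]; N <- d[4]; hw <- d[1] * d[2]
  Y <- one_hot4(labels, C)
  Pm <- matrix(probs$value, nrow = hw)     # columns (c, n)
  Ym <- matrix(Y, nrow = hw)
  inter <- colSums(Pm * Ym)
  sp <- colSums(Pm)
  sy <- colSums(Ym)
  num <- 2 * inter + smooth
  den <- sp + sy + smooth
  keep <- if (include_background) rep(TRUE, C) else c(FALSE, rep(TRUE, C - 1))
  keepm <- rep(keep, times = N)
  nterm <- sum(keep) * N
  val <- 1 - sum((num / den)[keepm]) / nterm
  tp_push(tp, val, backward = function(g) {
    ddice_dnum <- 1 / den
    ddice_dden <- -num / den^2
    scale <- ifelse(keepm, g / nterm, 0)
    dP <- sweep(Ym, 2, 2 * ddice_dnum * scale, "*") +
      matrix(rep(ddice_dden * scale, each = hw), nrow = hw)
    acc_grad(probs, array(-dP, d))
  })
}

## Feature-similarity loss between two branches (flattened tensors):
## cosine form 1 - (<a,b>+eps) / (|a||b|+eps); the literal printed form
## uses |a|^2 |b|^2 in place of |a||b|.
op_similarity <- function(tp, a, b, eps = 1e-5, form = c("cosine", "printed")) {
  form <- match.arg(form)
  av <- a$value; bv <- b$value
  s <- sum(av * bv)
  qa <- sum(av^2)
  qb <- sum(bv^2)
  if (form == "cosine") {
    root <- sqrt(qa * qb)
    den <- root + eps
    val <- 1 - (s + eps) / den
    tp_push(tp, val, backward = function(g) {
      dden_da <- if (root > 0) av * (qb / root) else av * 0
      dden_db <- if (root > 0) bv * (qa / root) else bv * 0
      acc_grad(a, g * (-(bv / den) + (s + eps) / den^2 * dden_da))
      acc_grad(b, g * (-(av / den) + (s + eps) / den^2 * dden_db))
    })
  } else {
    den <- qa * qb + eps
    val <- 1 - (s + eps) / den
    tp_push(tp, val, backward = function(g) {
      acc_grad(a, g * (-(bv / den) + (s + eps) / den^2 * (2 * av * qb)))
      acc_grad(b, g * (-(av / den) + (s + eps) / den^2 * (2 * bv * qa)))
    })
  }
}

## Scalar linear combination sum(w_i * node_i).
op_lincomb <- function(tp, xs, w) {
  val <- sum(vapply(seq_along(xs), function(i) w[i] * xs[[i]]$value, numeric(1)))
  tp_push(tp, val, backward = function(g) {
    for (i in seq_along(xs)) acc_grad(xs[[i]], g * w[i])
  })
}

## ---- optimiser -------------------------------------------------------------

#' One Adam update over a list of parameters
#'
#' Parameters with no accumulated gradient are skipped; gradients are cleared
#' after the step.
#' @keywords internal
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}
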