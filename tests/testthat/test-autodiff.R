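# Reverse-mode engine: analytic gradients against central differences, and
# structural traces (zero inputs, shared-parameter accumulation).

ns <- asNamespace("hafnet")

test_that("convolution gradients match central differences", {
  set.seed(1)
  for (geom in list(list(k = 3L, dil = 1L), list(k = 3L, dil = 2L),
                    list(k = 1L, dil = 1L))) {
    x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    W <- ns$new_param(matrix(rnorm(3 * geom$k^2 * 2, sd = 0.3), 3), "W")
    b <- ns$new_param(rnorm(3), "b")
    run <- function(xv, wv, bv) {
      tp <- ns$new_tape(FALSE)
      y <- ns$op_conv2d(tp, ns$op_input(tp, xv), ns$new_param(wv),
                        ns$new_param(bv), k = geom$k, dilation = geom$dil)
      sum(y$value^2)
    }
    tp <- ns$new_tape(FALSE)
    xn <- ns$op_input(tp, x)
    y <- ns$op_conv2d(tp, xn, W, b, k = geom$k, dilation = geom$dil)
    loss <- ns$tp_push(tp, sum(y$value^2),
                       backward = function(g) ns$acc_grad(y, g * 2 * y$value))
    ns$tape_backward(tp, loss)
    expect_grad_close(function(v) run(v, W$value, b$value), x, xn$grad, 1:8)
    expect_grad_close(function(v) run(x, v, b$value), W$value, W$grad,
                      seq_len(min(8, length(W$value))))
    expect_grad_close(function(v) run(x, W$value, v), b$value, b$grad, 1:3)
  }
})

test_that("transposed-conv, max-pool and batch-norm gradients are correct", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  Wt <- ns$new_param(matrix(rnorm(4 * 2 * 3, sd = 0.4), 8, 3), "Wt")
  gamma <- ns$new_param(runif(2, 0.5, 1.5), "gamma")
  beta <- ns$new_param(rnorm(2), "beta")
  fresh_state <- function() {
    st <- new.env()
    st$running_mean <- numeric(2)
    st$running_var <- rep(1, 2)
    st
  }
  run <- function(xv, wv, gv, bv) {
    tp <- ns$new_tape(TRUE)
    y <- ns$op_tconv2(tp, ns$op_input(tp, xv), ns$new_param(wv))
    y <- ns$op_batchnorm(tp, y, ns$new_param(gv), ns$new_param(bv),
                         fresh_state())
    y <- ns$op_maxpool2(tp, y)
    sum(y$value^3)
  }
  tp <- ns$new_tape(TRUE)
  xn <- ns$op_input(tp, x)
  y <- ns$op_tconv2(tp, xn, Wt)
  y <- ns$op_batchnorm(tp, y, gamma, beta, fresh_state())
  y <- ns$op_maxpool2(tp, y)
  loss <- ns$tp_push(tp, sum(y$value^3),
                     backward = function(g) ns$acc_grad(y, g * 3 * y$value^2))
  ns$tape_backward(tp, loss)
  expect_grad_close(function(v) run(v, Wt$value, gamma$value, beta$value),
                    x, xn$grad, 1:10)
  expect_grad_close(function(v) run(x, v, gamma$value, beta$value),
                    Wt$value, Wt$grad, 1:8)
  expect_grad_close(function(v) run(x, Wt$value, v, beta$value),
                    gamma$value, gamma$grad, 1:2)
  expect_grad_close(function(v) run(x, Wt$value, gamma$value, v),
                    beta$value, beta$grad, 1:2)
})

test_that("loss-op gradients (softmax, Dice, cross entropy, similarity) are correct", {
  set.seed(3)
  lg <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  lab <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  run <- function(v) {
    tp <- ns$new_tape(FALSE)
    x <- ns$op_input(tp, v)
    d <- ns$op_dice(tp, ns$op_softmax(tp, x), lab)
    ce <- ns$op_cross_entropy(tp, x, lab)
    ns$op_lincomb(tp, list(d, ce), c(1, 0.5))$value
  }
  tp <- ns$new_tape(FALSE)
  x <- ns$op_input(tp, lg)
  d <- ns$op_dice(tp, ns$op_softmax(tp, x), lab)
  ce <- ns$op_cross_entropy(tp, x, lab)
  loss <- ns$op_lincomb(tp, list(d, ce), c(1, 0.5))
  ns$tape_backward(tp, loss)
  expect_grad_close(run, lg, x$grad, seq(1, 96, by = 7), floor = 1e-3)

  a <- array(runif(24) + 0.1, c(2, 2, 3, 2))
  b <- array(runif(24) + 0.1, c(2, 2, 3, 2))
  for (form in c("cosine", "printed")) {
    runs <- function(av) {
      tp <- ns$new_tape(FALSE)
      ns$op_similarity(tp, ns$op_input(tp, av), ns$op_input(tp, b),
                       form = form)$value
    }
    tp <- ns$new_tape(FALSE)
    an <- ns$op_input(tp, a)
    sl <- ns$op_similarity(tp, an, ns$op_input(tp, b), form = form)
    ns$tape_backward(tp, sl)
    expect_grad_close(runs, a, an$grad, 1:10, floor = 1e-3)
  }
})

test_that("a parameter used twice on one tape accumulates both gradients", {
  W <- ns$new_param(matrix(0.5, 1, 1), "w")
  x <- array(1, c(2, 2, 1, 1))
  tp <- ns$new_tape(FALSE)
  xn <- ns$op_input(tp, x)
  y1 <- ns$op_conv2d(tp, xn, W, NULL, k = 1L)    # shared use 1
  y2 <- ns$op_conv2d(tp, xn, W, NULL, k = 1L)    # shared use 2
  s <- ns$op_add(tp, y1, y2)
  loss <- ns$tp_push(tp, sum(s$value),
                     backward = function(g) ns$acc_grad(s, array(g, dim(s$value))))
  ns$tape_backward(tp, loss)
  # d/dW of sum(2 * W * x) over 4 pixels = 8
  expect_equal(as.numeric(W$grad), 8, tolerance = 1e-6)
})

test_that("dropout is identity in inference mode and unbiased in training", {
  x <- array(runif(1000), c(10, 10, 10, 1))
  tp <- ns$new_tape(FALSE)
  out <- ns$op_dropout(tp, ns$op_input(tp, x), 0.5)
  expect_identical(out$value, x)
  set.seed(4)
  tp <- ns$new_tape(TRUE)
  out <- ns$op_dropout(tp, ns$op_input(tp, x), 0.2)
  kept <- out$value != 0
  expect_equal(mean(kept), 0.8, tolerance = 0.05)
  expect_equal(out$value[kept], x[kept] / 0.8)
})

test_that("fusion op gradients (sum/product/max parts) match central differences", {
  set.seed(5)
  xs <- lapply(1:3, function(i) array(runif(2 * 2 * 2 * 1, 0.2, 1.5),
                                      c(2, 2, 2, 1)))
  wts <- array(rnorm(2 * 2 * 6 * 1), c(2, 2, 6, 1))
  run <- function(vlist) {
    tp <- ns$new_tape(FALSE)
    nodes <- lapply(vlist, function(v) ns$op_input(tp, v))
    sum(ns$op_fuse(tp, nodes)$value * wts)
  }
  tp <- ns$new_tape(FALSE)
  nodes <- lapply(xs, function(v) ns$op_input(tp, v))
  f <- ns$op_fuse(tp, nodes)
  loss <- ns$tp_push(tp, sum(f$value * wts),
                     backward = function(g) ns$acc_grad(f, g * wts))
  ns$tape_backward(tp, loss)
  for (j in 1:3) {
    for (i in 1:8) {
      ng <- numeric_grad(function(v) { xs2 <- xs; xs2[[j]] <- v; run(xs2) },
                         xs[[j]], i, eps = 1e-5)
      expect_equal(nodes[[j]]$grad[i], ng, tolerance = 1e-4)
    }
  }
})
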