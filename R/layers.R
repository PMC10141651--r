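## Layer modules. A module is a list with $params (named hf_param list,
## possibly nested), optional $state (environment holding batch-norm running
## statistics), and $forward(tp, x, ...). Initialisation uses He-scaled
## normal draws from the caller's RNG stream, so building a network under
## set.seed() is fully reproducible.

he_init <- function(nrow, ncol, fan_in, name, gain = 2) {
  new_param(matrix(stats::rnorm(nrow * ncol, sd = sqrt(gain / fan_in)),
                   nrow, ncol), name = name)
}

#' Bare 2-D convolution module
#'
#' Kernel `k` x `k` at the given dilation; "same" padding so spatial size is
#' preserved at stride 1.
#' @keywords internal
sg_conv <- function(in_ch, out_ch, k = 3L, dilation = 1L, bias = TRUE,
                    name = "conv", gain = 1) {
  W <- he_init(out_ch, k * k * in_ch, k * k * in_ch, paste0(name, ".W"),
               gain = gain)
  b <- if (bias) new_param(numeric(out_ch), paste0(name, ".b"))
  params <- if (bias) list(W = W, b = b) else list(W = W)
  list(params = params, states = list(),
       forward = function(tp, x)
         op_conv2d(tp, x, W, b, k = k, dilation = dilation))
}

#' Convolution block: conv (no bias) -> batch norm -> ReLU
#' @keywords internal
sg_conv_block <- function(in_ch, out_ch, k = 3L, dilation = 1L,
                          name = "convblock") {
  W <- he_init(out_ch, k * k * in_ch, k * k * in_ch, paste0(name, ".W"),
               gain = 2)
  gamma <- new_param(rep(1, out_ch), paste0(name, ".gamma"))
  beta <- new_param(numeric(out_ch), paste0(name, ".beta"))
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(out_ch)
  state$running_var <- rep(1, out_ch)
  list(params = list(W = W, gamma = gamma, beta = beta), states = list(state),
       forward = function(tp, x) {
         y <- op_conv2d(tp, x, W, NULL, k = k, dilation = dilation)
         y <- op_batchnorm(tp, y, gamma, beta, state)
         op_relu(tp, y)
       })
}

#' Residual convolution: 1x1 projection + ConvBlock2(Dropout(ConvBlock1(x)))
#'
#' The projection (with bias) carries the identity path from `in_ch` to
#' `out_ch`; the residual path stacks two conv blocks with dropout between.
#' @keywords internal
sg_res_conv <- function(in_ch, out_ch, dropout_rate = 0.2, name = "resconv") {
  proj <- sg_conv(in_ch, out_ch, k = 1L, bias = TRUE, name = paste0(name, ".proj"))
  cb1 <- sg_conv_block(in_ch, out_ch, name = paste0(name, ".conv1"))
  cb2 <- sg_conv_block(out_ch, out_ch, name = paste0(name, ".conv2"))
  list(params = list(proj = proj$params, cb1 = cb1$params, cb2 = cb2$params),
       states = c(cb1$states, cb2$states),
       forward = function(tp, x) {
         p <- proj$forward(tp, x)
         h <- cb1$forward(tp, x)
         h <- op_dropout(tp, h, dropout_rate)
         h <- cb2$forward(tp, h)
         op_add(tp, p, h)
       })
}

#' Atrous spatial pyramid pooling bottleneck
#'
#' Parallel 3x3 convolutions at each dilation rate plus a global-average
#' pooling branch (1x1 conv, broadcast back); branch outputs are concatenated
#' and projected back to `C` channels by a 1x1 conv block.
#' @keywords internal
sg_aspp <- function(C, dilations = c(1L, 6L, 12L, 18L), name = "aspp") {
  branches <- lapply(seq_along(dilations), function(i)
    sg_conv_block(C, C, k = 3L, dilation = dilations[i],
                  name = paste0(name, ".d", dilations[i])))
  gapc <- sg_conv(C, C, k = 1L, bias = TRUE, name = paste0(name, ".gap"))
  proj <- sg_conv_block((length(dilations) + 1L) * C, C, k = 1L,
                        name = paste0(name, ".proj"))
  list(params = list(branches = lapply(branches, `[[`, "params"),
                     gap = gapc$params, proj = proj$params),
       states = c(do.call(c, lapply(branches, `[[`, "states")), proj$states),
       forward = function(tp, x) {
         d <- dim(x$value)
         outs <- lapply(branches, function(br) br$forward(tp, x))
         gp <- op_gap(tp, x)
         gp <- op_relu(tp, gapc$forward(tp, gp))
         gp <- op_broadcast_hw(tp, gp, d[1], d[2])
         proj$forward(tp, op_concat_c(tp, c(outs, list(gp))))
       })
}

#' Hybrid attentional fusion block
#'
#' Fuses n same-shaped C-channel modality maps into a 3C-channel map by
#' concatenating their elementwise sum, product and maximum, then applies a
#' soft-attention gate: out = phi3(F + F * sigmoid(phi2(relu(phi1(F))))),
#' all kernels 3x3. Output width is 3C for every n.
#' @keywords internal
sg_hafb <- function(C, clip = 1e6, name = "hafb") {
  phi1 <- sg_conv(3L * C, C, k = 3L, bias = TRUE, name = paste0(name, ".phi1"))
  phi2 <- sg_conv(C, 3L * C, k = 3L, bias = TRUE, name = paste0(name, ".phi2"))
  phi3 <- sg_conv(3L * C, 3L * C, k = 3L, bias = TRUE, name = paste0(name, ".phi3"))
  fuse <- function(tp, maps) op_fuse(tp, maps, clip = clip)
  forward_full <- function(tp, maps) {
    FF <- fuse(tp, maps)
    gate <- op_sigmoid(tp, phi2$forward(tp, op_relu(tp, phi1$forward(tp, FF))))
    out <- phi3$forward(tp, op_add(tp, FF, op_mul(tp, FF, gate)))
    list(out = out, gate = gate, fused = FF)
  }
  list(params = list(phi1 = phi1$params, phi2 = phi2$params,
                     phi3 = phi3$params),
       states = list(),
       fuse = fuse,
       forward_full = forward_full,
       forward = function(tp, maps) forward_full(tp, maps)$out)
}

#' Transposed-convolution module (kernel 2, stride 2)
#' @keywords internal
sg_tconv <- function(in_ch, out_ch, name = "tconv") {
  W <- new_param(matrix(stats::rnorm(4L * out_ch * in_ch,
                                     sd = sqrt(1 / (4 * in_ch))),
                        4L * out_ch, in_ch), paste0(name, ".W"))
  b <- new_param(numeric(out_ch), paste0(name, ".b"))
  list(params = list(W = W, b = b), states = list(),
       forward = function(tp, x) op_tconv2(tp, x, W, b))
}

## Flatten a nested module parameter structure into a list of hf_param.
collect_params <- function(x) {
  if (inherits(x, "hf_param")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}
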