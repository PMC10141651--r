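## Network assembly. Channel plan: encoder layer l outputs
## E_l = baseFilters * 2^(l-1); skip bundles carry k*E_l channels where the
## bundle multiplier k is 3 with the fusion block (sum/product/max
## concatenation fixes the width at 3C for any modality count), n for plain
## multi-modal concatenation, and 1 in single-encoder mode. The decoder and
## the merged bottleneck run at k times the encoder widths, so parameter
## counts are affine in n with the fusion block and quadratic without it.

bundle_multiplier <- function(cfg) {
  if (cfg@useHAFB) 3L
  else if (cfg@multiModal) cfg@nModalities
  else 1L
}

#' Channel plan of the assembled network
#'
#' @param cfg a \linkS4class{NetworkConfig}.
#' @return list with `encoder_out` (per-layer encoder channels),
#'   `bottleneck` (channels after the merge), and `decoder_out` (per-layer
#'   decoder channels, deepest last).
#' @examples
#' layerChannelPlan(networkConfig())
#' @export
layerChannelPlan <- function(cfg) {
  E <- cfg@baseFilters * 2L^(seq_len(cfg@nLayers) - 1L)
  k <- bundle_multiplier(cfg)
  list(encoder_out = E, bottleneck = k * E[cfg@nLayers], decoder_out = k * E)
}

#' Assemble the segmentation network
#'
#' Builds per-modality residual encoders (or one shared encoder in
#' single-encoder mode), per-modality atrous-pyramid bottlenecks, the
#' bottleneck merge, per-layer fusion blocks when enabled, and the decoder
#' with its classification head. All weights are drawn from the RNG, so
#' `seed` makes construction reproducible.
#'
#' @param cfg a \linkS4class{NetworkConfig}.
#' @param seed integer seed for weight initialisation.
#' @return a \linkS4class{SegNet}.
#' @examples
#' net <- buildNetwork(networkConfig(baseFilters = 4, nModalities = 2), seed = 1)
#' nParams(net)
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  e <- new.env(parent = emptyenv())
  with_seed(seed, {
    L <- cfg@nLayers
    E <- cfg@baseFilters * 2L^(seq_len(L) - 1L)
    k <- bundle_multiplier(cfg)
    n_enc <- if (cfg@multiModal) cfg@nModalities else 1L
    in0 <- if (cfg@multiModal) 1L else cfg@nModalities
    e$encoders <- lapply(seq_len(n_enc), function(m) {
      lapply(seq_len(L), function(l) {
        sg_res_conv(if (l == 1L) in0 else E[l - 1L], E[l], cfg@dropoutRate,
                    name = sprintf("enc%d.l%d", m, l))
      })
    })
    e$aspp <- lapply(seq_len(n_enc), function(m)
      sg_aspp(E[L], cfg@asppDilations, name = sprintf("aspp%d", m)))
    e$merge <- sg_res_conv(n_enc * E[L], k * E[L], cfg@dropoutRate,
                           name = "merge")
    e$hafb <- if (cfg@useHAFB)
      lapply(seq_len(L), function(l) sg_hafb(E[l], name = sprintf("hafb.l%d", l)))
    e$tconv <- lapply(seq_len(L), function(l)
      sg_tconv(if (l == L) k * E[L] else k * E[l + 1L], k * E[l],
               name = sprintf("dec%d.up", l)))
    e$dec <- lapply(seq_len(L), function(l)
      sg_res_conv(2L * k * E[l], k * E[l], cfg@dropoutRate,
                  name = sprintf("dec%d.res", l)))
    ## small-scale classifier head: starts near-uniform class scores
    e$endconv <- sg_conv(k * E[1L], cfg@nClasses, k = 3L, bias = TRUE,
                         name = "endconv", gain = 0.01)
  })
  new("SegNet", config = cfg, env = e)
}

net_param_list <- function(net) {
  e <- net@env
  collect_params(list(
    lapply(e$encoders, function(enc) lapply(enc, `[[`, "params")),
    lapply(e$aspp, `[[`, "params"),
    e$merge$params,
    if (!is.null(e$hafb)) lapply(e$hafb, `[[`, "params"),
    lapply(e$tconv, `[[`, "params"),
    lapply(e$dec, `[[`, "params"),
    e$endconv$params))
}

#' Number of learnable values in an assembled network
#' @param net a \linkS4class{SegNet}.
#' @export
nParams <- function(net) {
  sum(vapply(net_param_list(net), function(p) length(p$value), numeric(1)))
}

## ---- analytic parameter accounting ----------------------------------------

pc_conv <- function(i, o, k = 3, bias = TRUE) k^2 * i * o + if (bias) o else 0
pc_conv_block <- function(i, o, k = 3) k^2 * i * o + 2 * o
pc_res_conv <- function(i, o) pc_conv(i, o, 1) + pc_conv_block(i, o) +
  pc_conv_block(o, o)
pc_aspp <- function(C, nd) nd * pc_conv_block(C, C, 3) + pc_conv(C, C, 1) +
  pc_conv_block((nd + 1) * C, C, 1)
pc_hafb <- function(C) pc_conv(3 * C, C) + pc_conv(C, 3 * C) +
  pc_conv(3 * C, 3 * C)
pc_tconv <- function(i, o) 4 * i * o + o

#' Count learnable parameters of a configuration
#'
#' Closed-form accounting over the channel plan; agrees exactly with
#' \code{\link{nParams}} on the assembled network. With the fusion block the
#' count is affine in the number of modalities (skip bundles are fixed at 3C
#' channels); with plain concatenation the decoder width scales with the
#' modality count and the total is quadratic.
#'
#' @param cfg a \linkS4class{NetworkConfig}.
#' @return integer-valued numeric: the exact number of learnable values.
#' @examples
#' countParameters(networkConfig()) / 1e6
#' @export
countParameters <- function(cfg) {
  stopifnot(is(cfg, "NetworkConfig"))
  validObject(cfg)
  L <- cfg@nLayers
  E <- cfg@baseFilters * 2^(seq_len(L) - 1)
  k <- bundle_multiplier(cfg)
  n_enc <- if (cfg@multiModal) cfg@nModalities else 1L
  in0 <- if (cfg@multiModal) 1L else cfg@nModalities
  enc <- sum(vapply(seq_len(L), function(l)
    pc_res_conv(if (l == 1) in0 else E[l - 1], E[l]), numeric(1)))
  total <- n_enc * (enc + pc_aspp(E[L], length(cfg@asppDilations))) +
    pc_res_conv(n_enc * E[L], k * E[L])
  if (cfg@useHAFB) total <- total + sum(vapply(E, pc_hafb, numeric(1)))
  for (l in seq_len(L)) {
    total <- total + pc_tconv(if (l == L) k * E[L] else k * E[l + 1], k * E[l]) +
      pc_res_conv(2 * k * E[l], k * E[l])
  }
  total + pc_conv(k * E[1], cfg@nClasses, 3)
}

## ---- forward passes --------------------------------------------------------

## Encode a list of per-modality input nodes; returns skips[[m]][[l]]
## (pre-pool residual outputs) and bottleneck[[m]] (post-pyramid features).
network_encode <- function(net, tp, xs) {
  e <- net@env
  cfg <- net@config
  L <- cfg@nLayers
  n_enc <- length(e$encoders)
  if (length(xs) != n_enc)
    stop("expected ", n_enc, " input streams, got ", length(xs))
  skips <- vector("list", n_enc)
  bneck <- vector("list", n_enc)
  for (m in seq_len(n_enc)) {
    x <- xs[[m]]
    sk <- vector("list", L)
    for (l in seq_len(L)) {
      r <- e$encoders[[m]][[l]]$forward(tp, x)
      sk[[l]] <- r
      x <- op_maxpool2(tp, r)
    }
    skips[[m]] <- sk
    bneck[[m]] <- e$aspp[[m]]$forward(tp, x)
  }
  list(skips = skips, bottleneck = bneck)
}

## Decode from an encoding; skip bundles go through the fusion block when
## configured, else plain channel concatenation.
network_decode <- function(net, tp, enc, collect_gates = FALSE) {
  e <- net@env
  cfg <- net@config
  L <- cfg@nLayers
  y <- e$merge$forward(tp, op_concat_c(tp, enc$bottleneck))
  gates <- if (collect_gates) vector("list", L)
  for (l in rev(seq_len(L))) {
    y <- e$tconv[[l]]$forward(tp, y)
    maps <- lapply(enc$skips, `[[`, l)
    if (cfg@useHAFB) {
      full <- e$hafb[[l]]$forward_full(tp, maps)
      bundle <- full$out
      if (collect_gates) gates[[l]] <- full$gate
    } else {
      bundle <- if (length(maps) == 1L) maps[[1]] else op_concat_c(tp, maps)
    }
    y <- e$dec[[l]]$forward(tp, op_concat_c(tp, list(y, bundle)))
  }
  logits <- e$endconv$forward(tp, y)
  if (collect_gates) list(logits = logits, gates = gates) else logits
}

## Split a ModalityStack batch array into the network's input streams.
## stacks: list of ModalityStack with identical geometry.
stack_inputs <- function(net, tp, stacks) {
  cfg <- net@config
  nm <- cfg@nModalities
  d <- dim(labelMap(stacks[[1]]))
  N <- length(stacks)
  if (cfg@multiModal) {
    lapply(seq_len(nm), function(m) {
      a <- array(0, c(d[1], d[2], 1L, N))
      for (i in seq_len(N)) a[, , 1L, i] <- modalityImages(stacks[[i]])[[m]]
      op_input(tp, a)
    })
  } else {
    a <- array(0, c(d[1], d[2], nm, N))
    for (i in seq_len(N))
      for (m in seq_len(nm)) a[, , m, i] <- modalityImages(stacks[[i]])[[m]]
    list(op_input(tp, a))
  }
}

#' Full forward pass on a batch of cases
#'
#' @param net a \linkS4class{SegNet}.
#' @param stacks list of \linkS4class{ModalityStack} with identical geometry.
#' @param train logical; training mode (dropout, batch statistics).
#' @return list with `logits` (H,W,classes,N array) and `bottleneck`
#'   (H/2^L, W/2^L, C, N array of concatenated post-pyramid features).
#' @export
networkForward <- function(net, stacks, train = FALSE) {
  if (is(stacks, "ModalityStack")) stacks <- list(stacks)
  tp <- new_tape(train = train, grad = FALSE)
  xs <- stack_inputs(net, tp, stacks)
  enc <- network_encode(net, tp, xs)
  logits <- network_decode(net, tp, enc)
  list(logits = logits$value,
       bottleneck = op_concat_c(tp, enc$bottleneck)$value)
}
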