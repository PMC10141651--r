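## User-facing fusion utilities. The learnable fusion block itself is
## sg_hafb() in layers.R; these functions expose the fusion arithmetic and
## attention-map export on plain arrays.

#' Hybrid multi-strategy fusion of modality feature maps
#'
#' Channel-wise concatenation of the elementwise sum, elementwise product
#' and elementwise maximum over the input maps. Output has 3C channels for
#' any number of input maps, and is invariant to their order.
#'
#' @param maps list of same-shaped numeric arrays; either (H, W) matrices or
#'   (H, W, C, N) arrays.
#' @param clip magnitude at which the elementwise product part is clamped
#'   for numerical safety (products over many modalities can overflow).
#' @return array with 3C channels: for matrix inputs a (H, W, 3) array,
#'   otherwise (H, W, 3C, N).
#' @examples
#' f <- hybridFuse(list(matrix(1, 2, 2), matrix(2, 2, 2)))
#' f[1, 1, ]   # sum 3, product 2, max 2
#' @export
hybridFuse <- function(maps, clip = 1e6) {
  stopifnot(length(maps) >= 1)
  as_arr <- function(m) if (is.matrix(m)) array(m, c(dim(m), 1L, 1L)) else m
  xs <- lapply(maps, as_arr)
  d <- dim(xs[[1]])
  if (!all(vapply(xs, function(x) identical(dim(x), d), logical(1))))
    stop("all maps must share one shape")
  fuse_fwd_cpp(xs, clip)
}

#' Collapse an attention gate into a 2-D saliency map
#'
#' Channel-mean of the sigmoid gate, min-max rescaled to [0, 1] for overlay
#' rendering; a constant gate (degenerate range) maps to all zeros.
#'
#' @param gate (H, W, C, N) array of gate values (or an (H, W) matrix).
#' @param which sample index when N > 1.
#' @return H x W matrix with values in [0, 1].
#' @export
exportAttentionMap <- function(gate, which = 1L) {
  if (is.matrix(gate)) gate <- array(gate, c(dim(gate), 1L, 1L))
  d <- dim(gate)
  sal <- apply(gate[, , , which, drop = FALSE], c(1, 2), mean)
  rng <- range(sal)
  if (diff(rng) == 0) return(matrix(0, d[1], d[2]))
  (sal - rng[1]) / diff(rng)
}

#' Attention saliency maps of a trained network on one case
#'
#' Runs an inference forward pass collecting each skip-level fusion gate and
#' returns one saliency map per decoder level (level 1 at full resolution).
#' Requires a network built with the fusion block enabled.
#'
#' @param net a \linkS4class{SegNet} with `useHAFB = TRUE`.
#' @param stack a \linkS4class{ModalityStack}.
#' @return list of H_l x W_l saliency matrices, one per layer.
#' @export
networkAttentionMaps <- function(net, stack) {
  if (!net@config@useHAFB)
    stop("attention maps require a network with the fusion block enabled")
  tp <- new_tape(train = FALSE, grad = FALSE)
  xs <- stack_inputs(net, tp, list(stack))
  enc <- network_encode(net, tp, xs)
  dec <- network_decode(net, tp, enc, collect_gates = TRUE)
  lapply(dec$gates, function(g) exportAttentionMap(g$value))
}
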