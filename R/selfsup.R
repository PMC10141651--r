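## Masked dual-branch self-supervision: the clean case and a per-modality
## occluded copy pass through the SAME encoders and pyramid bottlenecks (one
## parameter set; gradients from both branches accumulate), the decoder
## consumes the clean branch, and a feature-similarity loss compares the two
## branches' concatenated bottleneck features.

#' Feature-similarity loss between two branches
#'
#' Cosine form `1 - (<a,b> + eps) / (|a|.|b| + eps)` over the flattened
#' feature bundles; identical branches score 0, orthogonal (disjoint
#' support) branches score ~1, and for nonnegative post-ReLU features the
#' value lies in [0, 1]. `form = "printed"` uses the squared norms
#' `|a|^2 |b|^2` in the denominator instead (under which identical inputs
#' generally do not score 0).
#'
#' @param a,b numeric arrays of identical shape.
#' @param eps smoothing coefficient (default 1e-5).
#' @param form "cosine" (default) or "printed".
#' @return scalar loss.
#' @examples
#' x <- array(runif(32), c(4, 4, 2, 1))
#' similarityLoss(x, x)    # ~0
#' @export
similarityLoss <- function(a, b, eps = 1e-5, form = c("cosine", "printed")) {
  if (!identical(dim(a), dim(b)))
    stop("branch features differ in shape")
  tp <- new_tape(train = FALSE, grad = FALSE)
  op_similarity(tp, op_input(tp, a), op_input(tp, b), eps = eps,
                form = match.arg(form))$value
}

#' Dual-branch forward pass
#'
#' Encodes the clean stack and an occluded copy with the shared encoders and
#' bottlenecks, decodes the segmentation from the clean branch only, and
#' returns both branches' concatenated bottleneck features for the
#' similarity loss.
#'
#' @param net a \linkS4class{SegNet}.
#' @param stacks list of \linkS4class{ModalityStack} (the clean batch).
#' @param strategy mask strategy (see \code{\link{makeMask}}).
#' @param seed RNG seed for mask placement.
#' @param fillValue masked-pixel intensity.
#' @param train logical; training mode.
#' @return list with `logits`, `cleanFeatures`, `maskedFeatures` (arrays)
#'   and `maskSpecs`.
#' @export
dualBranchForward <- function(net, stacks, strategy = "block20", seed = 1L,
                              fillValue = 0, train = FALSE) {
  if (is(stacks, "ModalityStack")) stacks <- list(stacks)
  tp <- new_tape(train = train, grad = train)
  masked <- lapply(seq_along(stacks), function(i)
    applyMasks(stacks[[i]], strategy, seed = seed + i - 1L, fillValue)$stack)
  xs_clean <- stack_inputs(net, tp, stacks)
  xs_mask <- stack_inputs(net, tp, masked)
  enc_c <- network_encode(net, tp, xs_clean)
  enc_m <- network_encode(net, tp, xs_mask)
  logits <- network_decode(net, tp, enc_c)
  list(logits = logits$value,
       cleanFeatures = op_concat_c(tp, enc_c$bottleneck)$value,
       maskedFeatures = op_concat_c(tp, enc_m$bottleneck)$value)
}
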