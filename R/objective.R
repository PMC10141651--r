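## Training losses (soft Dice + cross entropy mixture, similarity-augmented
## total) and evaluation metrics: per-region Dice, sensitivity, specificity
## and the 95th-percentile symmetric boundary Hausdorff distance for the
## clinically evaluated compositions WT (labels 1+2+3), TC (1+3), ET (3)
## (internal 3 stands for raw BraTS 4).

as_labels3 <- function(labels) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  labels
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c y_c) + s) / (sum p_c + sum y_c + s)` with the
#' class mean taken per sample and averaged over the batch; smoothing
#' `s = 1e-5` in numerator and denominator. Probabilities are
#' probability-weighted (soft), not thresholded.
#'
#' @param probs (H, W, C, N) array of class probabilities (or (H, W, C) for
#'   one sample); must sum to 1 per pixel.
#' @param labels integer labels in 0..C-1, shape (H, W, N) or (H, W).
#' @param smooth smoothing constant (default 1e-5).
#' @param includeBackground include class 0 in the class mean (default TRUE).
#' @return scalar in [0, 1 + smoothing tolerance].
#' @export
diceLoss <- function(probs, labels, smooth = 1e-5, includeBackground = TRUE) {
  if (length(dim(probs)) == 3L) probs <- array(probs, c(dim(probs), 1L))
  labels <- as_labels3(labels)
  tp <- new_tape(train = FALSE, grad = FALSE)
  op_dice(tp, op_input(tp, probs), labels, smooth = smooth,
          include_background = includeBackground)$value
}

#' Mean per-pixel cross entropy
#'
#' Negative log-likelihood of the true class under the channel-wise softmax
#' of the logits, averaged over pixels and batch.
#'
#' @param logits (H, W, C, N) or (H, W, C) array of unnormalised scores.
#' @param labels integer labels in 0..C-1.
#' @return scalar >= 0.
#' @examples
#' crossEntropyLoss(array(0, c(2, 2, 4)), matrix(0L, 2, 2))  # log(4)
#' @export
crossEntropyLoss <- function(logits, labels) {
  if (length(dim(logits)) == 3L) logits <- array(logits, c(dim(logits), 1L))
  labels <- as_labels3(labels)
  tp <- new_tape(train = FALSE, grad = FALSE)
  op_cross_entropy(tp, op_input(tp, logits), labels)$value
}

#' Combined segmentation loss
#'
#' Batch mean of `alpha * Dice + beta * crossEntropy` (defaults alpha = 1,
#' beta = 0.5); the normaliser is the batch size.
#'
#' @param logits (H, W, C, N) array (or (H, W, C)).
#' @param labels integer labels, shape (H, W, N) (or (H, W)).
#' @param alpha Dice weight (default 1).
#' @param beta cross-entropy weight (default 0.5).
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
segLoss <- function(logits, labels, alpha = 1, beta = 0.5, smooth = 1e-5) {
  if (length(dim(logits)) == 3L) logits <- array(logits, c(dim(logits), 1L))
  labels <- as_labels3(labels)
  if (dim(logits)[4] == 0L) stop("empty batch")
  tp <- new_tape(train = FALSE, grad = FALSE)
  lg <- op_input(tp, logits)
  dn <- op_dice(tp, op_softmax(tp, lg), labels, smooth = smooth)
  cn <- op_cross_entropy(tp, lg, labels)
  op_lincomb(tp, list(dn, cn), c(alpha, beta))$value
}

#' Total training objective
#'
#' @param seg segmentation loss value.
#' @param sim similarity loss value.
#' @param lambdaSim weight of the similarity term (default 1).
#' @return `seg + lambdaSim * sim`.
#' @export
totalLoss <- function(seg, sim, lambdaSim = 1) seg + lambdaSim * sim

#' Binary masks of the clinically evaluated tumor regions
#'
#' WT (whole tumor) = labels \{1,2,3\}; TC (tumor core, all structures
#' except edema) = \{1,3\}; ET (enhancing tumor) = \{3\}. By definition
#' ET is a subset of TC is a subset of WT.
#'
#' @param labels integer matrix/array with values in \{0,1,2,3\}.
#' @return list of logical objects `WT`, `TC`, `ET` of the input shape.
#' @export
regionMasks <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("invalid label value(s): ", paste(sort(bad), collapse = ", "))
  list(WT = array(labels %in% 1:3, dim(labels)),
       TC = array(labels %in% c(1L, 3L), dim(labels)),
       ET = array(labels == 3L, dim(labels)))
}

## boundary pixels of a 2-D logical mask: in the mask and 4-adjacent to a
## non-mask pixel or the image edge.
boundary_pixels <- function(mask) {
  d <- dim(mask)
  inner <- matrix(FALSE, d[1], d[2])
  if (d[1] > 2 && d[2] > 2) {
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1)
    inner[i, j] <- mask[i - 1, j] & mask[i + 1, j] &
      mask[i, j - 1] & mask[i, j + 1] & mask[i, j]
  }
  which(mask & !inner, arr.ind = TRUE)
}

#' 95th-percentile symmetric boundary Hausdorff distance
#'
#' Pools the two directed sets of nearest-boundary Euclidean distances
#' (prediction to truth and truth to prediction) and takes their 95th
#' percentile. Two empty regions give 0; one empty region gives `penalty`
#' (default: the image diagonal).
#'
#' @param pred,truth logical matrices (region masks).
#' @param percentile percentile of the pooled distances (default 95).
#' @param penalty distance returned when exactly one region is empty.
#' @return nonnegative scalar, in pixels.
#' @export
hd95 <- function(pred, truth, percentile = 95, penalty = NULL) {
  if (is.null(penalty)) penalty <- sqrt(sum(dim(pred)^2))
  pe <- !any(pred); te <- !any(truth)
  if (pe && te) return(0)
  if (pe || te) return(penalty)
  bp <- boundary_pixels(pred)
  bt <- boundary_pixels(truth)
  d2 <- outer(bp[, 1], bt[, 1], "-")^2 + outer(bp[, 2], bt[, 2], "-")^2
  dists <- c(sqrt(apply(d2, 1, min)), sqrt(apply(d2, 2, min)))
  unname(stats::quantile(dists, percentile / 100))
}

region_scores_one <- function(P, G, penalty) {
  tp <- sum(P & G); fp <- sum(P & !G); fn <- sum(!P & G); tn <- sum(!P & !G)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  sens <- if (tp + fn == 0) 1 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 1 else tn / (tn + fp)
  c(dice = dice, sensitivity = sens, specificity = spec,
    hd95 = hd95(P, G, penalty = penalty))
}

#' Evaluate a predicted label map against the truth
#'
#' Computes Dice, sensitivity, specificity and the 95th-percentile Hausdorff
#' distance for the WT, TC and ET region compositions.
#'
#' @param pred,truth integer matrices of internal labels \{0,1,2,3\}, same
#'   shape.
#' @param hdPenalty Hausdorff distance assigned when exactly one of the two
#'   regions is empty (default: image diagonal).
#' @return data.frame with one row per region and columns region, dice,
#'   sensitivity, specificity, hd95.
#' @examples
#' lab <- matrix(0L, 8, 8); lab[3:5, 3:5] <- 2L; lab[4, 4] <- 3L
#' evaluateSegmentation(lab, lab)
#' @export
evaluateSegmentation <- function(pred, truth, hdPenalty = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth differ in shape")
  if (is.null(hdPenalty)) hdPenalty <- sqrt(sum(dim(pred)^2))
  rp <- regionMasks(pred)
  rt <- regionMasks(truth)
  rows <- lapply(c("WT", "TC", "ET"), function(r)
    region_scores_one(rp[[r]], rt[[r]], hdPenalty))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(region = c("WT", "TC", "ET"), out)
  rownames(out) <- NULL
  out
}

#' Mean region scores over a list of cases
#'
#' @param scoreList list of data.frames from
#'   \code{\link{evaluateSegmentation}}.
#' @return data.frame of per-region means across cases.
#' @export
meanRegionScores <- function(scoreList) {
  stopifnot(length(scoreList) >= 1)
  out <- scoreList[[1]]
  num <- sapply(scoreList, function(s) as.matrix(s[, -1]),
                simplify = "array")
  out[, -1] <- apply(num, c(1, 2), mean)
  out
}
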