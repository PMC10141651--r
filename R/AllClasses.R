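#' @import methods
NULL

## ---- PhantomSpec -----------------------------------------------------------

#' Synthetic phantom specification
#'
#' Describes one synthetic multi-modal case: image side, number of
#' modalities, additive Gaussian noise level, the admissible range for the
#' whole-tumor pixel fraction, and the RNG seed that makes generation
#' bit-reproducible.
#'
#' @slot imageSide image side in pixels (>= 32).
#' @slot nModalities number of co-registered modality images (>= 1).
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot tumorFractionRange length-2 numeric in (0,1): admissible fraction
#'   of tumor (nonzero-label) pixels.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
         representation(imageSide = "integer", nModalities = "integer",
                        noiseSd = "numeric", tumorFractionRange = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@imageSide < 32L) msg <- c(msg, "imageSide must be >= 32")
  if (object@nModalities < 1L) msg <- c(msg, "nModalities must be >= 1")
  tfr <- object@tumorFractionRange
  if (length(tfr) != 2L || any(tfr <= 0) || any(tfr >= 1) || tfr[1] > tfr[2])
    msg <- c(msg, "tumorFractionRange must be an increasing pair in (0,1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param imageSide image side in pixels (default 64).
#' @param nModalities number of modalities (default 4).
#' @param noiseSd Gaussian noise standard deviation (default 0.05).
#' @param tumorFractionRange admissible whole-tumor pixel fraction
#'   (default c(0.05, 0.15)).
#' @param seed RNG seed (default 1).
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(imageSide = 64, seed = 7)
#' @export
phantomSpec <- function(imageSide = 64L, nModalities = 4L, noiseSd = 0.05,
                        tumorFractionRange = c(0.05, 0.15), seed = 1L) {
  new("PhantomSpec", imageSide = as.integer(imageSide),
      nModalities = as.integer(nModalities), noiseSd = as.numeric(noiseSd),
      tumorFractionRange = as.numeric(tumorFractionRange),
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %dx%d, %d modalities, noise sd %.3g, tumor fraction [%.3g, %.3g], seed %d\n",
              object@imageSide, object@imageSide, object@nModalities,
              object@noiseSd, object@tumorFractionRange[1],
              object@tumorFractionRange[2], object@seed))
})

## ---- ModalityStack ---------------------------------------------------------

#' One case's co-registered multi-modal slice
#'
#' Holds one 2-D image per modality plus an integer label map on the internal
#' encoding \{0,1,2,3\}: 0 background, 1 necrotic/non-enhancing core,
#' 2 peritumoral edema, 3 enhancing tumor (3 stands for the BraTS raw
#' label 4).
#'
#' @slot images list of same-shaped numeric matrices, one per modality.
#' @slot labels integer matrix, values in \{0,1,2,3\}.
#' @slot modalities character vector of modality names.
#' @export
setClass("ModalityStack",
         representation(images = "list", labels = "matrix",
                        modalities = "character"))

setValidity("ModalityStack", function(object) {
  msg <- character(0)
  if (!length(object@images)) msg <- c(msg, "at least one modality image")
  dims <- unique(lapply(object@images, dim))
  if (length(dims) != 1L) msg <- c(msg, "all modality images must share one shape")
  else if (!identical(as.integer(dims[[1]]), as.integer(dim(object@labels))))
    msg <- c(msg, "labels must share the image shape")
  bad <- setdiff(unique(as.vector(object@labels)), 0:3)
  if (length(bad)) msg <- c(msg, paste("invalid label values:",
                                       paste(bad, collapse = ", ")))
  if (length(object@modalities) != length(object@images))
    msg <- c(msg, "one modality name per image")
  if (length(msg)) msg else TRUE
})

#' Construct a ModalityStack
#' @param images list of numeric matrices (one per modality).
#' @param labels integer matrix with values in \{0,1,2,3\}.
#' @param modalities modality names (default t1, t1ce, flair, t2 recycled).
#' @return a \linkS4class{ModalityStack}.
#' @export
modalityStack <- function(images, labels,
                          modalities = c("t1", "t1ce", "flair", "t2")[seq_along(images)]) {
  storage.mode(labels) <- "integer"
  new("ModalityStack", images = images, labels = labels,
      modalities = as.character(modalities))
}

#' @describeIn modalityStack the per-modality image list.
#' @param x a ModalityStack.
#' @export
modalityImages <- function(x) x@images

#' @describeIn modalityStack the integer label map.
#' @export
labelMap <- function(x) x@labels

#' Number of modalities
#' @param x a ModalityStack.
#' @export
setGeneric("nModalities", function(x) standardGeneric("nModalities"))

#' @rdname nModalities
setMethod("nModalities", "ModalityStack", function(x) length(x@images))

setMethod("show", "ModalityStack", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = 0:3))
  cat(sprintf("ModalityStack: %dx%d, modalities [%s]\n", d[1], d[2],
              paste(object@modalities, collapse = ", ")))
  cat(sprintf("  label counts 0/1/2/3: %s (tumor fraction %.3f)\n",
              paste(tab, collapse = "/"), sum(object@labels > 0) / prod(d)))
})

## ---- NetworkConfig ---------------------------------------------------------

#' Architectural hyperparameters
#'
#' @slot nModalities number of input modalities.
#' @slot nLayers encoder/decoder depth (pool/upsample stages).
#' @slot baseFilters channels of the first encoder layer; later layers double.
#' @slot nClasses segmentation classes (background + 3 tumor sub-regions).
#' @slot asppDilations dilation rates of the atrous pyramid bottleneck.
#' @slot dropoutRate dropout inside residual blocks.
#' @slot useHAFB gate skip connections through the hybrid attentional
#'   fusion block (skip bundles of 3C channels) instead of plain
#'   concatenation (nC channels).
#' @slot multiModal one encoder per modality (TRUE) or a single encoder over
#'   channel-stacked modalities (FALSE).
#' @export
setClass("NetworkConfig",
         representation(nModalities = "integer", nLayers = "integer",
                        baseFilters = "integer", nClasses = "integer",
                        asppDilations = "integer", dropoutRate = "numeric",
                        useHAFB = "logical", multiModal = "logical"))

setValidity("NetworkConfig", function(object) {
  msg <- character(0)
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
  if (object@nModalities < 1L) msg <- c(msg, "nModalities must be >= 1")
  dil <- object@asppDilations
  if (any(dil < 1L) || anyDuplicated(dil))
    msg <- c(msg, "asppDilations must be positive and distinct")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkConfig
#'
#' Defaults follow the reference configuration: 4 modalities, 4 layers,
#' 32 base filters, 4 classes, pyramid dilations 1/6/12/18, dropout 0.2,
#' fusion block on, one encoder per modality.
#'
#' @param nModalities,nLayers,baseFilters,nClasses,asppDilations,dropoutRate,useHAFB,multiModal
#'   see the class slots.
#' @return a \linkS4class{NetworkConfig}.
#' @examples
#' networkConfig(baseFilters = 8, nModalities = 2)
#' @export
networkConfig <- function(nModalities = 4L, nLayers = 4L, baseFilters = 32L,
                          nClasses = 4L, asppDilations = c(1L, 6L, 12L, 18L),
                          dropoutRate = 0.2, useHAFB = TRUE,
                          multiModal = TRUE) {
  new("NetworkConfig", nModalities = as.integer(nModalities),
      nLayers = as.integer(nLayers), baseFilters = as.integer(baseFilters),
      nClasses = as.integer(nClasses),
      asppDilations = as.integer(asppDilations),
      dropoutRate = as.numeric(dropoutRate), useHAFB = isTRUE(useHAFB),
      multiModal = isTRUE(multiModal))
}

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf("NetworkConfig: %d modalities (%s), %d layers, base %d, %d classes\n",
              object@nModalities,
              if (object@multiModal) "multi-encoder" else "single encoder",
              object@nLayers, object@baseFilters, object@nClasses))
  cat(sprintf("  ASPP dilations [%s], dropout %.2f, HAFB %s\n",
              paste(object@asppDilations, collapse = ","),
              object@dropoutRate, if (object@useHAFB) "on" else "off"))
})

## ---- MaskSpec --------------------------------------------------------------

#' Geometry of one occlusion mask
#'
#' @slot strategy one of block20, block50, grid, random.
#' @slot windowOrigin 0-based (row, col) of the mask window's top-left pixel.
#' @slot seed RNG seed used to draw the mask.
#' @slot fillValue intensity written into masked pixels.
#' @export
setClass("MaskSpec",
         representation(strategy = "character", windowOrigin = "integer",
                        seed = "integer", fillValue = "numeric"))

setValidity("MaskSpec", function(object) {
  if (!object@strategy %in% c("block20", "block50", "grid", "random"))
    return("strategy must be block20, block50, grid or random")
  if (length(object@windowOrigin) != 2L || any(object@windowOrigin < 0L))
    return("windowOrigin must be a nonnegative (row, col) pair")
  TRUE
})

setMethod("show", "MaskSpec", function(object) {
  cat(sprintf("MaskSpec: %s at (%d, %d), fill %.3g, seed %d\n",
              object@strategy, object@windowOrigin[1], object@windowOrigin[2],
              object@fillValue, object@seed))
})

## ---- TrainConfig -----------------------------------------------------------

#' Training hyperparameters
#'
#' Defaults follow the reference schedule: Adam, batch size 8, initial
#' learning rate 1e-5 decayed by 0.9 every 5 epochs, 15 epochs, Dice weight
#' alpha = 1 and cross-entropy weight beta = 0.5, self-supervision on with
#' 20x20 block masks.
#'
#' @slot batchSize samples per optimisation step.
#' @slot initialLr initial Adam learning rate.
#' @slot lrDecay multiplicative decay factor.
#' @slot decayEvery epochs between decays.
#' @slot epochs total training epochs.
#' @slot optimizer optimiser name ("adam").
#' @slot dataFraction fraction of the training cases used (low-data runs).
#' @slot seed RNG seed for shuffling, dropout, masks and initialisation.
#' @slot selfsup enable the masked dual-branch pretext task.
#' @slot maskStrategy block20, block50, grid or random.
#' @slot maskFill intensity written into masked pixels.
#' @slot lambdaSim weight of the similarity loss in the total objective.
#' @slot alpha Dice-loss weight in the segmentation loss.
#' @slot beta cross-entropy weight in the segmentation loss.
#' @slot epsilon smoothing coefficient of the similarity loss.
#' @export
setClass("TrainConfig",
         representation(batchSize = "integer", initialLr = "numeric",
                        lrDecay = "numeric", decayEvery = "integer",
                        epochs = "integer", optimizer = "character",
                        dataFraction = "numeric", seed = "integer",
                        selfsup = "logical", maskStrategy = "character",
                        maskFill = "numeric", lambdaSim = "numeric",
                        alpha = "numeric", beta = "numeric",
                        epsilon = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "lrDecay must be in (0,1]")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@dataFraction <= 0 || object@dataFraction > 1)
    msg <- c(msg, "dataFraction must be in (0,1]")
  if (!object@maskStrategy %in% c("block20", "block50", "grid", "random"))
    msg <- c(msg, "unknown maskStrategy")
  if (any(c(object@lambdaSim, object@alpha, object@beta) < 0))
    msg <- c(msg, "loss weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param batchSize,initialLr,lrDecay,decayEvery,epochs,optimizer,dataFraction,seed,selfsup,maskStrategy,maskFill,lambdaSim,alpha,beta,epsilon
#'   see the class slots.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(batchSize = 8L, initialLr = 1e-5, lrDecay = 0.9,
                        decayEvery = 5L, epochs = 15L, optimizer = "adam",
                        dataFraction = 1.0, seed = 1L, selfsup = TRUE,
                        maskStrategy = "block20", maskFill = 0,
                        lambdaSim = 1.0, alpha = 1.0, beta = 0.5,
                        epsilon = 1e-5) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      initialLr = as.numeric(initialLr), lrDecay = as.numeric(lrDecay),
      decayEvery = as.integer(decayEvery), epochs = as.integer(epochs),
      optimizer = as.character(optimizer),
      dataFraction = as.numeric(dataFraction), seed = as.integer(seed),
      selfsup = isTRUE(selfsup), maskStrategy = as.character(maskStrategy),
      maskFill = as.numeric(maskFill), lambdaSim = as.numeric(lambdaSim),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      epsilon = as.numeric(epsilon))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: %s, batch %d, lr %.2g (x%.2g every %d epochs), %d epochs\n",
              object@optimizer, object@batchSize, object@initialLr,
              object@lrDecay, object@decayEvery, object@epochs))
  cat(sprintf("  selfsup %s (%s masks, fill %.3g, lambda %.3g), alpha %.3g beta %.3g, data fraction %.2f, seed %d\n",
              if (object@selfsup) "on" else "off", object@maskStrategy,
              object@maskFill, object@lambdaSim, object@alpha, object@beta,
              object@dataFraction, object@seed))
})

## ---- SegNet ----------------------------------------------------------------

#' Assembled segmentation network
#'
#' Wraps the layer modules, their learnable parameters and batch-norm state
#' in an environment; use \code{\link{buildNetwork}} to construct,
#' \code{\link{nParams}} to count learnable values and
#' \code{\link{predictCase}} for inference.
#'
#' @slot config the \linkS4class{NetworkConfig} the network was built from.
#' @slot env environment holding modules and parameters.
#' @export
setClass("SegNet",
         representation(config = "NetworkConfig", env = "environment"))

setMethod("show", "SegNet", function(object) {
  cat("SegNet (residual encoder-decoder with",
      if (object@config@useHAFB) "hybrid attentional fusion)" else "concatenation skips)", "\n")
  show(object@config)
  cat(sprintf("  learnable values: %s\n", format(nParams(object), big.mark = ",")))
})
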