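## BraTS-style preprocessing: middle-slice selection, center cropping, label
## remapping between the raw encoding {0,1,2,4} and the internal contiguous
## encoding {0,1,2,3}, and per-slice z-score normalisation over the brain
## (nonzero) region. Axial slices are taken along the third array axis.

#' Select the middle run of axial slices
#'
#' Keeps the centered `n` slices along the third axis; for depth D the
#' retained 0-based index range is `[floor((D-n)/2), floor((D-n)/2)+n)`.
#' Volumes shallower than `n` are returned whole with a warning.
#'
#' @param volume 3-D array (height, width, depth).
#' @param n number of slices to retain (default 144).
#' @return list of 2-D matrices with attribute `sliceIndices` (0-based
#'   indices into the input volume).
#' @examples
#' v <- array(rnorm(8 * 8 * 155), c(8, 8, 155))
#' s <- selectSlices(v)
#' length(s)                     # 144
#' range(attr(s, "sliceIndices")) # 5 148
#' @export
selectSlices <- function(volume, n = 144L) {
  if (length(dim(volume)) != 3L)
    stop("selectSlices expects a 3-D array, got ",
         length(dim(volume)), " dimensions")
  D <- dim(volume)[3]
  if (D < n) {
    warning("volume depth ", D, " < ", n, "; returning all slices")
    idx <- seq_len(D)
  } else {
    start <- (D - n) %/% 2L
    idx <- start + seq_len(n)
  }
  out <- lapply(idx, function(i) volume[, , i])
  attr(out, "sliceIndices") <- as.integer(idx - 1L)
  out
}

#' Center-crop a slice to a square window
#'
#' For input side S the crop offset is `floor((S - targetSide)/2)` on each
#' axis.
#'
#' @param slice 2-D matrix.
#' @param targetSide output side in pixels (default 224).
#' @return targetSide x targetSide matrix with attribute `cropOffset`
#'   (0-based row/col offsets into the input).
#' @export
centerCrop <- function(slice, targetSide = 224L) {
  d <- dim(slice)
  if (is.null(d) || length(d) != 2L) stop("centerCrop expects a 2-D matrix")
  if (any(d < targetSide))
    stop("input ", d[1], "x", d[2], " smaller than crop target ", targetSide)
  off <- (d - targetSide) %/% 2L
  out <- slice[off[1] + seq_len(targetSide), off[2] + seq_len(targetSide),
               drop = FALSE]
  attr(out, "cropOffset") <- as.integer(off)
  out
}

#' Remap raw BraTS labels to the internal contiguous encoding
#'
#' 4 becomes 3; 0, 1, 2 are unchanged. Any other value is a data error.
#'
#' @param labels integer matrix/array with values in \{0,1,2,4\}.
#' @return same-shaped integer object with values in \{0,1,2,3\}.
#' @seealso \code{\link{bratsLabels}} for the inverse map.
#' @export
remapLabels <- function(labels) {
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, c(0, 1, 2, 4))
  if (length(bad))
    stop("unexpected label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected subset of {0, 1, 2, 4})")
  out <- labels
  out[labels == 4] <- 3L
  storage.mode(out) <- "integer"
  out
}

#' Restore the raw BraTS label encoding
#'
#' Inverse of \code{\link{remapLabels}}: 3 becomes 4.
#'
#' @param labels integer matrix/array with values in \{0,1,2,3\}.
#' @return same-shaped integer object with values in \{0,1,2,4\}.
#' @export
bratsLabels <- function(labels) {
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, 0:3)
  if (length(bad))
    stop("unexpected label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected subset of {0, 1, 2, 3})")
  out <- labels
  out[labels == 3] <- 4L
  storage.mode(out) <- "integer"
  out
}

#' Z-score a slice over its nonzero (brain) region
#'
#' Pixels with exactly zero raw intensity are treated as background and stay
#' zero; the remaining pixels are standardised to mean 0, sd 1. A constant
#' nonzero region maps to 0.
#'
#' @param image 2-D numeric matrix.
#' @return matrix of the same shape.
#' @export
normalizeSlice <- function(image) {
  mask <- image != 0
  if (!any(mask)) return(image * 0)
  v <- image[mask]
  s <- stats::sd(v)
  out <- image * 0
  out[mask] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
  out
}

#' Read a BraTS-style NIfTI case from disk
#'
#' Files are keyed by the suffix convention `<caseId>_<modality>.nii[.gz]`
#' with modalities t1, t1ce, flair, t2 and labels `<caseId>_seg.nii[.gz]`.
#' Missing modalities are skipped; a missing label file yields NULL labels.
#'
#' @param dir directory holding the case files (searched non-recursively).
#' @param caseId case identifier prefix.
#' @param modalities modality suffixes to read.
#' @return list with `modalities` (named list of 3-D arrays), `labels`
#'   (3-D integer array or NULL) and `caseId`.
#' @export
readBratsCase <- function(dir, caseId,
                          modalities = c("t1", "t1ce", "flair", "t2")) {
  find1 <- function(suffix) {
    for (ext in c(".nii.gz", ".nii")) {
      f <- file.path(dir, paste0(caseId, "_", suffix, ext))
      if (file.exists(f)) return(f)
    }
    NULL
  }
  vols <- list()
  for (m in modalities) {
    f <- find1(m)
    if (!is.null(f)) vols[[m]] <- as.array(RNifti::readNifti(f))
  }
  if (!length(vols)) stop("no modality files for case '", caseId, "' in ", dir)
  shapes <- unique(lapply(vols, dim))
  if (length(shapes) != 1L) stop("modality volumes differ in shape")
  segf <- find1("seg")
  labels <- if (!is.null(segf)) {
    lab <- as.array(RNifti::readNifti(segf))
    storage.mode(lab) <- "integer"
    lab
  }
  list(modalities = vols, labels = labels, caseId = caseId)
}

#' Build a slice dataset from raw cases
#'
#' Applies the preprocessing pipeline per case: middle-slice selection,
#' center crop, label remapping, and (optionally) per-slice per-modality
#' z-score normalisation. Slices with an empty brain mask are kept.
#'
#' @param cases list of raw cases as returned by \code{\link{readBratsCase}}
#'   (labels required).
#' @param nSlices slices retained per case (default 144).
#' @param targetSide crop side (default 224).
#' @param normalize z-score each slice over its nonzero region (default TRUE).
#' @return list of \linkS4class{ModalityStack}; attribute `provenance` is a
#'   data.frame of (caseId, sliceIndex) per entry, slice indices 0-based and
#'   strictly increasing within a case.
#' @export
sliceDataset <- function(cases, nSlices = 144L, targetSide = 224L,
                         normalize = TRUE) {
  out <- list()
  prov_case <- character(0)
  prov_idx <- integer(0)
  for (case in cases) {
    if (is.null(case$labels)) stop("case '", case$caseId, "' has no labels")
    modn <- names(case$modalities)
    sel <- lapply(case$modalities, selectSlices, n = nSlices)
    lab_sel <- selectSlices(case$labels, n = nSlices)
    idx <- attr(lab_sel, "sliceIndices")
    for (i in seq_along(lab_sel)) {
      imgs <- lapply(sel, function(sl) {
        x <- centerCrop(sl[[i]], targetSide)
        if (normalize) x <- normalizeSlice(x)
        x
      })
      lab <- remapLabels(centerCrop(lab_sel[[i]], targetSide))
      out[[length(out) + 1L]] <- modalityStack(unname(imgs), lab, modn)
      prov_case <- c(prov_case, case$caseId)
      prov_idx <- c(prov_idx, idx[i])
    }
  }
  attr(out, "provenance") <- data.frame(caseId = prov_case,
                                        sliceIndex = prov_idx)
  out
}

#' Write a predicted label slice back in the original frame
#'
#' Re-embeds a cropped prediction into the full slice frame by zero-padding
#' at the stored crop offset, restores the raw BraTS label encoding, and
#' writes NIfTI.
#'
#' @param pred integer matrix of internal labels \{0,1,2,3\} (the crop).
#' @param path output file path (.nii or .nii.gz).
#' @param frameSide side of the original frame (default 240).
#' @param cropOffset 0-based row/col offsets of the crop (default centered).
#' @return invisibly, the output path.
#' @export
writePrediction <- function(pred, path, frameSide = 240L, cropOffset = NULL) {
  d <- dim(pred)
  if (is.null(cropOffset)) cropOffset <- (c(frameSide, frameSide) - d) %/% 2L
  full <- matrix(0L, frameSide, frameSide)
  full[cropOffset[1] + seq_len(d[1]), cropOffset[2] + seq_len(d[2])] <-
    bratsLabels(pred)
  RNifti::writeNifti(full, path)
  invisible(path)
}
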