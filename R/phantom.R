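## Synthetic multi-modal phantom cases with BraTS-like structure: a brain
## disc carrying nested elliptical tumor sub-regions (edema > core >
## enhancing), rendered in each modality with a distinct per-class intensity
## profile plus Gaussian noise. The profiles are chosen so that no single
## modality separates all classes (T1CE highlights enhancing tumor, FLAIR
## edema, T2 core and edema), which makes multi-modal fusion measurably
## useful in training tests.

## class x modality mean intensities; rows = classes 0..3 (background brain,
## necrotic core, edema, enhancing), columns = t1, t1ce, flair, t2.
phantom_class_means <- function() {
  matrix(c(0.45, 0.40, 0.35, 0.30,   # brain tissue
           0.30, 0.40, 0.55, 0.70,   # necrotic / non-enhancing core
           0.50, 0.45, 0.80, 0.70,   # peritumoral edema
           0.45, 0.85, 0.55, 0.50),  # enhancing tumor
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("class", 0:3),
                         c("t1", "t1ce", "flair", "t2")))
}

ellipse_mask <- function(side, center, a, b, angle) {
  rr <- matrix(seq_len(side), side, side)
  cc <- t(rr)
  X <- cc - center[2]
  Y <- rr - center[1]
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

## Ellipse intersected with `inside`, axis-rescaled until its pixel count
## lands in [lo, hi] (fractions of side^2); returns a logical mask.
fit_ellipse <- function(side, inside, center, area, ecc, angle, lo, hi) {
  a <- sqrt(area / (pi * ecc))
  b <- ecc * a
  mask <- ellipse_mask(side, center, a, b, angle) & inside
  for (i in 1:15) {
    cnt <- sum(mask)
    frac <- cnt / side^2
    if (frac >= lo && frac <= hi) break
    target <- (lo + hi) / 2 * side^2
    scale <- if (cnt == 0) 1.3 else sqrt(target / cnt)
    a <- a * scale
    b <- b * scale
    mask <- ellipse_mask(side, center, a, b, angle) & inside
  }
  mask
}

#' Generate one synthetic multi-modal case
#'
#' Produces nested elliptical tumor regions — an edema region (class 2)
#' containing a necrotic core (class 1) containing an enhancing blob
#' (class 3) — on a brain disc; each modality renders the same geometry with
#' its own per-class mean-intensity profile plus additive Gaussian noise.
#' Pixels outside the brain disc are exactly zero. Deterministic given the
#' spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{ModalityStack}; the fraction of nonzero-label
#'   pixels lies inside `tumorFractionRange`.
#' @examples
#' case <- generateCase(phantomSpec(imageSide = 64, seed = 3))
#' case
#' @export
generateCase <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  s <- spec@imageSide
  with_seed(spec@seed, {
    ctr <- c((s + 1) / 2, (s + 1) / 2)
    brain <- ellipse_mask(s, ctr, 0.46 * s, 0.42 * s, stats::runif(1, 0, pi))
    lo <- spec@tumorFractionRange[1]
    hi <- spec@tumorFractionRange[2]
    f <- stats::runif(1, lo, hi)
    wt_ctr <- ctr + stats::runif(2, -0.12 * s, 0.12 * s)
    wt <- fit_ellipse(s, brain, wt_ctr, f * s^2,
                      stats::runif(1, 0.6, 1), stats::runif(1, 0, pi), lo, hi)
    wt_cnt <- sum(wt)
    core_ctr <- wt_ctr + stats::runif(2, -0.04 * s, 0.04 * s)
    core <- fit_ellipse(s, wt, core_ctr, 0.45 * wt_cnt,
                        stats::runif(1, 0.6, 1), stats::runif(1, 0, pi),
                        0.30 * wt_cnt / s^2, 0.60 * wt_cnt / s^2)
    enh_ctr <- core_ctr + stats::runif(2, -0.02 * s, 0.02 * s)
    enh <- fit_ellipse(s, core, enh_ctr, 0.40 * sum(core),
                       stats::runif(1, 0.6, 1), stats::runif(1, 0, pi),
                       0.20 * sum(core) / s^2, 0.60 * sum(core) / s^2)
    labels <- matrix(0L, s, s)
    labels[wt] <- 2L
    labels[core] <- 1L
    labels[enh] <- 3L
    mu <- phantom_class_means()
    nm <- spec@nModalities
    mods <- c(colnames(mu), if (nm > 4) paste0("m", 5:nm))[seq_len(nm)]
    images <- lapply(seq_len(nm), function(m) {
      col <- (m - 1L) %% 4L + 1L
      shift <- 0.03 * ((m - 1L) %/% 4L)
      img <- matrix(0, s, s)
      for (cls in 0:3) {
        sel <- if (cls == 0L) brain & labels == 0L else labels == cls
        img[sel] <- mu[cls + 1L, col] + shift
      }
      img[brain] <- img[brain] + stats::rnorm(sum(brain), 0, spec@noiseSd)
      img
    })
    modalityStack(images, labels, mods)
  })
}

#' Stack per-slice phantoms into a 3-D volume with raw BraTS labels
#'
#' Slice i is generated from the spec with seed `seed + i - 1`, so depth 1
#' reproduces \code{\link{generateCase}} exactly. The returned label volume
#' uses the raw BraTS encoding \{0,1,2,4\}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param depth number of axial slices (>= 1).
#' @return list with `modalities` (named list of side x side x depth arrays)
#'   and `labels` (integer array of the same shape, values in \{0,1,2,4\}).
#' @export
generateVolume <- function(spec, depth) {
  stopifnot(is(spec, "PhantomSpec"))
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  s <- spec@imageSide
  nm <- spec@nModalities
  vols <- NULL
  labs <- array(0L, c(s, s, depth))
  for (i in seq_len(depth)) {
    sl <- generateCase(phantomSpec(s, nm, spec@noiseSd,
                                   spec@tumorFractionRange,
                                   spec@seed + i - 1L))
    if (is.null(vols)) {
      vols <- lapply(sl@modalities, function(m) array(0, c(s, s, depth)))
      names(vols) <- sl@modalities
    }
    for (m in seq_len(nm)) vols[[m]][, , i] <- modalityImages(sl)[[m]]
    lab <- labelMap(sl)
    lab[lab == 3L] <- 4L
    labs[, , i] <- lab
  }
  list(modalities = vols, labels = labs)
}

#' Write a phantom volume as a BraTS-style NIfTI case
#'
#' Emits one file per modality (`<caseId>_<modality>.nii.gz`) and a label
#' file (`<caseId>_seg.nii.gz`) into `dir/caseId/`, matching the
#' suffix-keyed reader \code{\link{readBratsCase}}.
#'
#' @param volume output of \code{\link{generateVolume}}.
#' @param dir output directory.
#' @param caseId case identifier used for the file names.
#' @return invisibly, the case directory path.
#' @export
writeCaseNifti <- function(volume, dir, caseId) {
  cdir <- file.path(dir, caseId)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(volume$modalities))
    RNifti::writeNifti(volume$modalities[[m]],
                       file.path(cdir, sprintf("%s_%s.nii.gz", caseId, m)))
  RNifti::writeNifti(volume$labels,
                     file.path(cdir, sprintf("%s_seg.nii.gz", caseId)))
  invisible(cdir)
}

#' Generate a list of phantom cases
#'
#' Case i uses seed `spec@seed + i - 1`.
#'
#' @param n number of cases.
#' @param spec template \linkS4class{PhantomSpec}.
#' @return list of \linkS4class{ModalityStack}.
#' @export
phantomDataset <- function(n, spec = phantomSpec()) {
  lapply(seq_len(n), function(i)
    generateCase(phantomSpec(spec@imageSide, spec@nModalities, spec@noiseSd,
                             spec@tumorFractionRange, spec@seed + i - 1L)))
}
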