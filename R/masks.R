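## Occlusion masks for the self-supervised pretext task. Four strategies:
##   block20 - one 20x20 square (400 px);
##   block50 - one 50x50 square (2500 px);
##   grid    - 4x4 = 16 squares of 5x5 on a 10-pixel period inside a 35x35
##             window (block top-left offsets {0,10,20,30}^2; 400 px);
##   random  - 400 distinct pixels sampled uniformly inside a 35x35 window.
## The window origin is drawn uniformly over valid positions.

mask_footprint <- function(strategy) {
  switch(strategy, block20 = 20L, block50 = 50L, grid = 35L, random = 35L,
         stop("unknown mask strategy '", strategy, "'"))
}

## Draw a window origin (0-based) for a strategy on an imageSide image.
draw_origin <- function(strategy, imageSide) {
  w <- mask_footprint(strategy)
  if (imageSide < w)
    stop("image side ", imageSide, " too small for the ", strategy,
         " mask footprint (", w, ")")
  c(sample.int(imageSide - w + 1L, 1L) - 1L,
    sample.int(imageSide - w + 1L, 1L) - 1L)
}

mask_from_origin <- function(strategy, imageSide, origin) {
  mask <- matrix(FALSE, imageSide, imageSide)
  w <- mask_footprint(strategy)
  r0 <- origin[1]; c0 <- origin[2]
  if (strategy %in% c("block20", "block50")) {
    mask[r0 + seq_len(w), c0 + seq_len(w)] <- TRUE
  } else if (strategy == "grid") {
    for (dr in c(0L, 10L, 20L, 30L))
      for (dc in c(0L, 10L, 20L, 30L))
        mask[r0 + dr + 1:5, c0 + dc + 1:5] <- TRUE
  } else {                                 # random
    pix <- sample.int(35L * 35L, 400L)     # without replacement
    rr <- (pix - 1L) %% 35L
    cc <- (pix - 1L) %/% 35L
    mask[cbind(r0 + rr + 1L, c0 + cc + 1L)] <- TRUE
  }
  mask
}

#' Build one occlusion mask
#'
#' @param strategy one of "block20", "block50", "grid", "random".
#' @param imageSide image side in pixels.
#' @param seed RNG seed for the window origin (and pixel draw for "random").
#' @param fillValue intensity recorded in the returned spec.
#' @return list with `mask` (logical imageSide x imageSide matrix) and
#'   `spec` (a \linkS4class{MaskSpec}).
#' @examples
#' m <- makeMask("grid", 224, seed = 1)
#' sum(m$mask)   # 400
#' @export
makeMask <- function(strategy, imageSide, seed = 1L, fillValue = 0) {
  imageSide <- as.integer(imageSide)
  with_seed(seed, {
    origin <- draw_origin(strategy, imageSide)
    mask <- mask_from_origin(strategy, imageSide, origin)
    list(mask = mask,
         spec = new("MaskSpec", strategy = strategy,
                    windowOrigin = as.integer(origin),
                    seed = as.integer(seed),
                    fillValue = as.numeric(fillValue)))
  })
}

#' Occlude each modality of a case at a distinct position
#'
#' Every modality receives its own mask; window origins are re-drawn until
#' pairwise distinct, so different modalities are occluded at different
#' positions and can supply complementary information. Masked pixels are set
#' to `fillValue`; labels are untouched.
#'
#' @param stack a \linkS4class{ModalityStack}.
#' @param strategy mask strategy (see \code{\link{makeMask}}).
#' @param seed RNG seed; the whole placement is deterministic given it.
#' @param fillValue intensity written into masked pixels (default 0, the
#'   post-normalisation background level).
#' @return list with `stack` (the masked \linkS4class{ModalityStack}) and
#'   `specs` (list of \linkS4class{MaskSpec}, one per modality).
#' @export
applyMasks <- function(stack, strategy = "block20", seed = 1L, fillValue = 0) {
  stopifnot(is(stack, "ModalityStack"))
  side <- dim(labelMap(stack))[1]
  nm <- nModalities(stack)
  w <- mask_footprint(strategy)
  npos <- as.numeric(side - w + 1L)^2
  if (npos < nm)
    stop("image side ", side, " admits only ", npos,
         " distinct ", strategy, " origins for ", nm, " modalities")
  with_seed(seed, {
    origins <- list()
    tries <- 0L
    while (length(origins) < nm) {
      o <- draw_origin(strategy, side)
      if (!any(vapply(origins, identical, logical(1), y = o))) {
        origins[[length(origins) + 1L]] <- o
      } else {
        tries <- tries + 1L
        if (tries > 10000L) stop("cannot place pairwise-distinct masks")
      }
    }
    masks <- lapply(origins, function(o) mask_from_origin(strategy, side, o))
    images <- modalityImages(stack)
    for (m in seq_len(nm)) images[[m]][masks[[m]]] <- fillValue
    specs <- lapply(seq_len(nm), function(m)
      new("MaskSpec", strategy = strategy,
          windowOrigin = as.integer(origins[[m]]), seed = as.integer(seed),
          fillValue = as.numeric(fillValue)))
    list(stack = modalityStack(images, labelMap(stack), stack@modalities),
         specs = specs, masks = masks)
  })
}
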