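# Stage 1: initial inter-section alignment. Acquisitions are ranked by
# Michelson contrast; within each slab the highest-contrast group is
# chained rigidly outward from the central section, then progressively
# lower-contrast groups are aligned against the already-fixed sections.

#' Rank acquisitions by Michelson contrast
#'
#' Per-acquisition score = median of per-section Michelson contrasts
#' (aggregation statistic configurable); groups are ordered highest first,
#' ties broken alphabetically by label.
#'
#' @param stack a [SectionStack].
#' @param images named list of [Image2D]s keyed by image ref.
#' @param masks named list of binary [GMMask2D]s keyed by image ref.
#' @param aggregate summary statistic over sections (default median).
#' @return list `scores` (named numeric, descending), `order` (acquisition
#'   labels, highest contrast first).
#' @export
rankAcquisitions <- function(stack, images, masks,
                             aggregate = stats::median) {
  rec <- stack@records[stack@records$qc_pass, ]
  stopifnot(nrow(rec) >= 1)
  per <- vapply(seq_len(nrow(rec)), function(i) {
    key <- rec$image[i]
    tryCatch(michelsonContrast(images[[key]], masks[[key]]),
             error = function(e) NA_real_)
  }, numeric(1))
  byAcq <- tapply(per, rec$acquisition, function(x)
    aggregate(x[is.finite(x)]))
  byAcq[!is.finite(byAcq)] <- 0
  ord <- order(-unlist(byAcq), names(byAcq))   # ties: alphabetical
  scores <- unlist(byAcq)[ord]
  list(scores = scores, order = names(scores))
}

# reference choice: nearest fixed section by |sample difference|, ties
# toward the slab centre
.nearestFixed <- function(sample, fixedSamples, centerSample) {
  d <- abs(fixedSamples - sample)
  best <- which(d == min(d))
  if (length(best) > 1)
    best <- best[which.min(abs(fixedSamples[best] - centerSample))]
  best[1]
}

#' Chain-align the sections of one slab with rigid 2D transforms
#'
#' Within the highest-contrast acquisition group the central section is
#' fixed (identity); moving outward in both directions each section aligns
#' to its nearest already-fixed same-group neighbour toward the centre and
#' then becomes fixed. Each subsequent lower-contrast group aligns every
#' section to the nearest fixed section of the higher-ranked groups, which
#' collectively serve as its reference, until all sections are aligned.
#' Lower-contrast sections never serve as references for higher-contrast
#' ones.
#'
#' @param stackSlab a [SectionStack] restricted to one slab.
#' @param masks named list of [GMMask2D]s keyed by image ref.
#' @param ranking output of [rankAcquisitions()] (or NULL for a single
#'   group).
#' @param grid common in-plane grid (list dim/spacing/origin) the masks are
#'   placed on before registration; default the grid of the first mask.
#' @param maxRotDeg rotation search range passed to the registration.
#' @return named list of [Rigid2D] keyed by image ref (centre = grid
#'   centre); attribute `"flagged"` lists sections whose optimiser
#'   diverged (identity kept).
#' @export
chainAlignSlab <- function(stackSlab, masks, ranking = NULL, grid = NULL,
                           maxRotDeg = 15) {
  rec <- stackSlab@records[stackSlab@records$qc_pass, ]
  if (nrow(rec) == 0) stop("chainAlignSlab: empty slab")
  if (is.null(grid)) {
    m0 <- masks[[rec$image[1]]]
    grid <- list(dim = dim(m0@values), spacing = m0@spacing,
                 origin = m0@origin)
  }
  gridImg <- Image2D(matrix(0, grid$dim[1], grid$dim[2]),
                     spacing = grid$spacing, origin = grid$origin)
  groups <- if (is.null(ranking)) unique(rec$acquisition) else ranking$order

  out <- list()
  flagged <- character(0)
  fixedKeys <- character(0)
  fixedSamples <- numeric(0)
  alignedMask <- list()   # fixed sections' masks on the common grid
  centerSample <- stats::median(rec$sample)

  placed <- function(key) {
    m <- masks[[key]]
    applyTransform2D(m, out[[key]], outGrid = gridImg, mode = "linear")
  }

  for (gi in seq_along(groups)) {
    g <- rec[rec$acquisition == groups[gi], , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$sample), , drop = FALSE]
    if (gi == 1 && length(fixedKeys) == 0) {
      # central section (lower of the two middle samples for even counts)
      cIdx <- ceiling(nrow(g) / 2)
      cKey <- g$image[cIdx]
      out[[cKey]] <- Rigid2D(center = .imageCenter(gridImg))
      fixedKeys <- cKey
      fixedSamples <- g$sample[cIdx]
      alignedMask[[cKey]] <- placed(cKey)
      rest <- g[-cIdx, , drop = FALSE]
      rest <- rest[order(abs(rest$sample - g$sample[cIdx])), , drop = FALSE]
    } else {
      rest <- g
    }
    if (nrow(rest) == 0) next
    newKeys <- character(0); newSamples <- numeric(0)
    for (i in seq_len(nrow(rest))) {
      key <- rest$image[i]
      refIdx <- .nearestFixed(rest$sample[i], fixedSamples, centerSample)
      refKey <- fixedKeys[refIdx]
      t <- registerRigid2D(masks[[key]], alignedMask[[refKey]],
                           maxRotDeg = maxRotDeg)
      if (!isTRUE(attr(t, "converged"))) flagged <- c(flagged, key)
      out[[key]] <- t
      if (gi == 1) {
        # first group: sections become references immediately (chaining)
        fixedKeys <- c(fixedKeys, key)
        fixedSamples <- c(fixedSamples, rest$sample[i])
        alignedMask[[key]] <- placed(key)
      } else {
        newKeys <- c(newKeys, key)
        newSamples <- c(newSamples, rest$sample[i])
      }
    }
    # lower-contrast group joins the fixed set only once fully aligned
    for (k in seq_along(newKeys)) {
      fixedKeys <- c(fixedKeys, newKeys[k])
      fixedSamples <- c(fixedSamples, newSamples[k])
      alignedMask[[newKeys[k]]] <- placed(newKeys[k])
    }
  }
  attr(out, "flagged") <- flagged
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Common in-plane grid covering a set of section images
#' @param images named list of [Image2D]s.
#' @param resMm target pixel size (mm).
#' @return list `dim`, `spacing`, `origin`.
#' @export
commonInPlaneGrid <- function(images, resMm) {
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (img in images) {
    a <- img@origin - img@spacing / 2
    b <- img@origin + (dim(img@values) - 0.5) * img@spacing
    lo <- pmin(lo, a); hi <- pmax(hi, b)
  }
  dims <- pmax(1L, as.integer(round((hi - lo) / resMm)))
  list(dim = dims, spacing = rep(resMm, 2), origin = lo + resMm / 2)
}

#' Build the initial volume by stacking rigidly aligned sections
#'
#' Sections (or their GM masks) are resampled through their rigid
#' transforms onto a common in-plane grid at `resMm` and stacked at world
#' position `sample x section thickness` along the cutting axis; planes
#' with no acquired section are background 0.
#'
#' @param stack a [SectionStack].
#' @param rigids named list of [Rigid2D] keyed by image ref.
#' @param images named list of [Image2D] / [GMMask2D] to stack.
#' @param resMm in-plane output resolution (mm); the plane spacing stays at
#'   the section thickness.
#' @param mode resampling mode.
#' @return a [Volume3D] (or [GMMask3D] when the inputs are masks) with
#'   cutting axis 2.
#' @export
buildInitialVolume <- function(stack, rigids, images, resMm,
                               mode = "linear") {
  rec <- stack@records[stack@records$qc_pass, ]
  grid <- commonInPlaneGrid(images[rec$image], resMm)
  thick <- rec$section_thickness_um[1] / 1000
  samples <- rec$sample
  planeIdx <- samples - min(samples) + 1L
  nPlane <- max(planeIdx)
  arr <- array(0, c(grid$dim[1], nPlane, grid$dim[2]))
  isMask <- is(images[[rec$image[1]]], "GMMask2D")
  for (i in seq_len(nrow(rec))) {
    key <- rec$image[i]
    t <- rigids[[key]] %||% Rigid2D()
    img <- applyTransform2D(images[[key]], t,
                            outGrid = list(dim = grid$dim,
                                           spacing = grid$spacing,
                                           origin = grid$origin),
                            mode = mode)
    arr[, planeIdx[i], ] <- img@values
  }
  origin <- c(grid$origin[1], min(samples) * thick, grid$origin[2])
  if (isMask) GMMask3D(pmin(pmax(arr, 0), 1),
                       spacing = c(resMm, thick, resMm), origin = origin,
                       isBinary = FALSE)
  else Volume3D(arr, spacing = c(resMm, thick, resMm), origin = origin)
}
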