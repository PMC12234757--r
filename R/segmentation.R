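# Contrast-agnostic GM segmentation: a synthetic-contrast training-image
# generator for learned segmenters (domain randomisation over tissue-class
# intensities, laminar structure, skull presence and augmentations), a
# pluggable Segmenter interface, the classical Otsu fallback, and
# segmentation evaluation.

#' Recipe for synthetic-contrast training images
#'
#' Defaults follow the generator's standard protocol: 10,000 images, 500
#' sections per randomly transformed volume, per-axis scaling U(0.9, 1.1),
#' rotations U(0, 15) degrees, 0-11 cortical layers with random
#' proportional (Dirichlet) thicknesses, skull retained in 50% of examples,
#' and random smoothing/noise/intensity-scale/crop augmentation.
#'
#' @param nImages total number of training pairs.
#' @param sectionsPerVolume sections drawn per transformed volume.
#' @param scaleRange,rotationRangeDeg affine augmentation ranges.
#' @param layerCountRange integer range of cortical layer counts.
#' @param skullProb probability a synthetic skull ring is retained.
#' @param classMeans,classSds named intensity model (Gaussian per class) for
#'   `wm`, `gm`, `insideBg`, `skull`; layer values are drawn around the gm
#'   entry. Intensities are 8-bit gray levels.
#' @param blurSigmaRange,noiseSdRange,intensityScaleRange,cropFraction
#'   augmentation parameter ranges.
#' @param seed root seed for [generateTrainingSet()].
#' @return a validated recipe list.
#' @export
synthRecipe <- function(nImages = 10000L, sectionsPerVolume = 500L,
                        scaleRange = c(0.9, 1.1),
                        rotationRangeDeg = c(0, 15),
                        layerCountRange = c(0L, 11L), skullProb = 0.5,
                        classMeans = c(wm = 60, gm = 150, insideBg = 15,
                                       skull = 220),
                        classSds = c(wm = 20, gm = 45, insideBg = 8,
                                     skull = 25),
                        blurSigmaRange = c(0, 1.5),
                        noiseSdRange = c(0, 8),
                        intensityScaleRange = c(0.8, 1.2),
                        cropFraction = 0.05, seed = 0L) {
  stopifnot(scaleRange[1] <= scaleRange[2], skullProb >= 0, skullProb <= 1,
            layerCountRange[1] >= 0, nImages >= 1, sectionsPerVolume >= 1)
  list(nImages = as.integer(nImages),
       sectionsPerVolume = as.integer(sectionsPerVolume),
       scaleRange = scaleRange, rotationRangeDeg = rotationRangeDeg,
       layerCountRange = as.integer(layerCountRange),
       skullProb = skullProb, classMeans = classMeans, classSds = classSds,
       blurSigmaRange = blurSigmaRange, noiseSdRange = noiseSdRange,
       intensityScaleRange = intensityScaleRange,
       cropFraction = cropFraction, seed = as.integer(seed))
}

#' Segmenter: the pluggable GM-segmentation interface
#'
#' Any callable honouring this interface can stand in for the learned
#' segmenter: it receives an [Image2D] and must return a binary [GMMask2D]
#' on the same grid. The bundled classical implementation is
#' [otsuSegmenter()]; a trained network is wrapped the same way.
#'
#' @slot name segmenter label used in logs.
#' @slot predictFun function(Image2D) -> GMMask2D.
#' @export
setClass("Segmenter",
  representation(name = "character", predictFun = "function"))

#' @param name label.
#' @param predictFun prediction function.
#' @return a `Segmenter`.
#' @rdname Segmenter-class
#' @export
Segmenter <- function(name, predictFun)
  new("Segmenter", name = name, predictFun = predictFun)

#' Run a segmenter on one section image
#' @param segmenter a [Segmenter].
#' @param img an [Image2D].
#' @return a binary [GMMask2D] on the grid of `img`.
#' @export
segmenterPredict <- function(segmenter, img) {
  out <- segmenter@predictFun(img)
  if (!is(out, "GMMask2D") ||
      !identical(dim(out@values), dim(img@values)))
    stop("segmenter '", segmenter@name,
         "' violated the interface (grid or type mismatch)")
  out
}

setMethod("show", "Segmenter", function(object)
  cat(sprintf("Segmenter '%s'\n", object@name)))

# ---- random affine on a label volume -----------------------------------

.randomAffineLabels <- function(labelVolume, recipe) {
  sc <- stats::runif(3, recipe$scaleRange[1], recipe$scaleRange[2])
  ang <- stats::runif(1, recipe$rotationRangeDeg[1],
                      recipe$rotationRangeDeg[2])
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  a <- .deg2rad(ang)
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  A <- R %*% diag(sc)
  center <- labelVolume@origin +
    (dim(labelVolume@values) - 1) / 2 * labelVolume@spacing
  Minv <- solve(A)
  g <- .volGridPoints(labelVolume, 1L)
  src <- sweep(sweep(g$pts, 2, center) %*% t(Minv), 2, center, `+`)
  vals <- sampleAt(labelVolume, src, mode = "nearest")
  Volume3D(array(vals, dim(labelVolume@values)),
           spacing = labelVolume@spacing, origin = labelVolume@origin,
           cutAxis = labelVolume@cutAxis)
}

# cortical depth fraction within a 2D slice: 0 at the WM border, 1 at the
# outer border, via distance transforms
.corticalDepth2 <- function(lab) {
  gm <- lab == 2
  if (!any(gm)) return(matrix(0, nrow(lab), ncol(lab)))
  big <- sum(dim(lab))
  # distance to the WM / outside-background class; a plane missing one of
  # them (e.g. a cap slice with no WM) gets a large constant instead
  dWM <- if (any(lab == 1))
    EBImage::imageData(EBImage::distmap(EBImage::as.Image(1 * (lab != 1))))
  else matrix(big, nrow(lab), ncol(lab))
  dBG <- if (any(lab == 0))
    EBImage::imageData(EBImage::distmap(EBImage::as.Image(1 * (lab != 0))))
  else matrix(big, nrow(lab), ncol(lab))
  depth <- dWM / pmax(dWM + dBG, 1e-9)
  depth[!gm] <- 0
  depth
}

#' Synthesize one training image / label pair
#'
#' Applies one random affine (per-axis scaling, rotation about a random
#' axis) to the label volume, extracts a random tissue-bearing plane,
#' subdivides the cortex into `k ~ U{0..11}` layers with Dirichlet
#' proportional thicknesses, assigns every class a Gaussian-random gray
#' value, optionally keeps a synthetic skull ring, and applies smoothing /
#' noise / intensity-scale / crop augmentations. The paired label image
#' has classes background 0, WM 1, cortex 2, and a boundary channel
#' marking pixels at class interfaces.
#'
#' @param labelVolume a [Volume3D] of integer labels (0 background, 1 WM,
#'   2 cortex).
#' @param recipe a [synthRecipe()].
#' @param drawSeed seed of this draw (fixed seed, identical pair).
#' @return list `image` ([Image2D], 8-bit range), `labels` ([Image2D] of
#'   classes), `boundary` ([Image2D] 0/1), `meta` (draw parameters).
#' @export
synthesizeTrainingPair <- function(labelVolume, recipe = synthRecipe(),
                                   drawSeed = 0L) {
  if (!any(labelVolume@values == 2))
    stop("synthesizeTrainingPair: label volume has no cortex class")
  withr::with_seed(as.integer(drawSeed), {
    tv <- .randomAffineLabels(labelVolume, recipe)
    planes <- which(apply(tv@values == 2, tv@cutAxis, sum) > 0)
    j <- planes[sample.int(length(planes), 1)]
    lab <- extractPlane(tv, j)@values
    .renderTrainingPlane(lab, recipe, spacing = tv@spacing[-tv@cutAxis])
  })
}

.renderTrainingPlane <- function(lab, recipe, spacing = c(1, 1)) {
  k <- sample(seq(recipe$layerCountRange[1], recipe$layerCountRange[2]), 1)
  img <- matrix(0, nrow(lab), ncol(lab))
  rnd <- function(cls) stats::rnorm(1, recipe$classMeans[[cls]],
                                    recipe$classSds[[cls]])
  img[lab == 1] <- rnd("wm")
  img[lab == 0] <- rnd("insideBg") * (stats::runif(1) < 0.5)
  gmSel <- lab == 2
  if (k <= 1) {
    img[gmSel] <- rnd("gm")
  } else {
    depth <- .corticalDepth2(lab)
    prop <- stats::rgamma(k, 1, 1)           # Dirichlet(1,...,1)
    cuts <- c(0, cumsum(prop / sum(prop)))
    layer <- cut(depth[gmSel], breaks = cuts, include.lowest = TRUE,
                 labels = FALSE)
    layerVals <- stats::rnorm(k, recipe$classMeans[["gm"]],
                              recipe$classSds[["gm"]])
    img[gmSel] <- layerVals[layer]
  }
  hasSkull <- stats::runif(1) < recipe$skullProb
  if (hasSkull) {
    # skull ring: background pixels 2-4 px from the tissue boundary
    dd <- EBImage::imageData(EBImage::distmap(EBImage::as.Image(1 * (lab == 0))))
    skullBand <- lab == 0 & dd >= 2 & dd <= 4
    img[skullBand] <- rnd("skull")
  }
  # augmentations
  sig <- stats::runif(1, recipe$blurSigmaRange[1], recipe$blurSigmaRange[2])
  if (sig > 0.05) img <- .gaussSmooth(img, sig)
  img <- img * stats::runif(1, recipe$intensityScaleRange[1],
                            recipe$intensityScaleRange[2])
  nz <- stats::runif(1, recipe$noiseSdRange[1], recipe$noiseSdRange[2])
  img <- img + stats::rnorm(length(img), 0, nz)
  crop <- floor(recipe$cropFraction * dim(lab) * stats::runif(2))
  if (any(crop > 0)) {
    img[seq_len(crop[1]), ] <- 0; lab[seq_len(crop[1]), ] <- 0
    img[, seq_len(crop[2])] <- 0; lab[, seq_len(crop[2])] <- 0
  }
  img <- pmin(pmax(img, 0), 255)
  boundary <- .classBoundary(lab)
  list(image = Image2D(img, spacing = spacing),
       labels = Image2D(lab, spacing = spacing),
       boundary = Image2D(1 * boundary, spacing = spacing),
       meta = list(layers = k, skull = hasSkull))
}

.classBoundary <- function(lab) {
  b <- matrix(FALSE, nrow(lab), ncol(lab))
  for (ax in 1:2) for (s in c(-1L, 1L))
    b <- b | (.shiftAxis(lab, ax, s) != lab)
  b
}

#' Generate a training set on disk
#'
#' Writes `nImages` image/label/boundary PNG triplets plus an index CSV.
#' Sections are grouped `sectionsPerVolume` per random volume transform;
#' the whole set is a deterministic function of `recipe$seed`.
#'
#' @param labelVolume label volume as in [synthesizeTrainingPair()].
#' @param recipe a [synthRecipe()]; use small `nImages` for smoke tests.
#' @param dir output directory.
#' @return data.frame index (also written to `<dir>/index.csv`),
#'   invisibly.
#' @export
generateTrainingSet <- function(labelVolume, recipe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nVol <- ceiling(recipe$nImages / recipe$sectionsPerVolume)
  rows <- vector("list", recipe$nImages)
  i <- 0L
  for (vIdx in seq_len(nVol)) {
    nHere <- min(recipe$sectionsPerVolume, recipe$nImages - i)
    tv <- withr::with_seed(recipe$seed + vIdx,
                           .randomAffineLabels(labelVolume, recipe))
    planes <- which(apply(tv@values == 2, tv@cutAxis, sum) > 0)
    for (s in seq_len(nHere)) {
      i <- i + 1L
      pair <- withr::with_seed(recipe$seed + 100003L * i, {
        j <- planes[sample.int(length(planes), 1)]
        .renderTrainingPlane(extractPlane(tv, j)@values, recipe,
                             spacing = tv@spacing[-tv@cutAxis])
      })
      img <- sprintf("img_%05d.png", i)
      labf <- sprintf("lab_%05d.png", i)
      bndf <- sprintf("bnd_%05d.png", i)
      writeSectionImage(pair$image, file.path(dir, img))
      png::writePNG(pair$labels@values / 255, file.path(dir, labf))
      png::writePNG(pair$boundary@values, file.path(dir, bndf))
      rows[[i]] <- data.frame(id = i, image = img, labels = labf,
                              boundary = bndf, volume = vIdx,
                              layers = pair$meta$layers,
                              skull = pair$meta$skull)
    }
  }
  idx <- do.call(rbind, rows)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

# ---- Otsu thresholding --------------------------------------------------

#' Otsu threshold of an image over a 256-bin histogram
#'
#' Maximises the between-class variance over all 256 candidate thresholds
#' (ties broken toward the lowest bin). Values are binned over \[0, 255\]
#' for 8-bit-range images, otherwise over the value range.
#'
#' @param values numeric vector or matrix with at least 2 distinct values.
#' @return list `threshold` (value separating the classes: x > threshold
#'   is the bright class), `bin` (0-based bin index), `breaks`.
#' @export
otsuThreshold <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2)
    stop("otsuThreshold: degenerate input (constant image)")
  lo <- if (min(v) >= 0 && max(v) <= 255) 0 else min(v)
  hi <- if (min(v) >= 0 && max(v) <= 255) 255 else max(v)
  breaks <- seq(lo, hi, length.out = 257)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                          1L), 256L), 256L)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[256]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[1:255]                # threshold after bin t, t in 1..255
  t <- which.max(sb)             # which.max takes the first (lowest) tie
  list(threshold = breaks[t + 1], bin = t - 1L, breaks = breaks)
}

# ribbon-likeness of a candidate tissue mask. Two ingredients: the tissue
# side should not own the image border (the dark background always does in
# preprocessed sections), and a cortical ribbon is a large connected
# component with low solidity (area well below its convex hull area).
.ribbonScore <- function(mask) {
  if (!any(mask)) return(-Inf)
  border <- mean(c(mask[1, ], mask[nrow(mask), ], mask[, 1],
                   mask[, ncol(mask)]))
  labm <- EBImage::bwlabel(EBImage::as.Image(1 * mask))
  tab <- tabulate(as.integer(labm))
  big <- which.max(tab)
  comp <- EBImage::imageData(labm) == big
  idx <- which(comp, arr.ind = TRUE)
  if (nrow(idx) < 3) return(0)
  hull <- grDevices::chull(idx)
  hp <- idx[hull, , drop = FALSE]
  hullArea <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                      hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  solidity <- nrow(idx) / max(hullArea, nrow(idx))
  nrow(idx) * (1 - solidity) * (1 - border)^2
}

#' Otsu-threshold GM segmentation of a section
#'
#' Thresholds the 256-bin histogram at the between-class-variance maximum
#' and keeps the configured side. Side "auto" picks whichever side looks
#' more like a cortical ribbon (largest connected component with low
#' solidity); acquisitions with inverted contrast then segment correctly
#' without per-acquisition configuration.
#'
#' @param img an [Image2D] with at least 2 distinct values.
#' @param tissueSide "auto", "bright" or "dark".
#' @param clean keep only the largest connected component and fill small
#'   (noise) holes.
#' @param refineWithinTissue when the thresholded side is disc-like (the
#'   split fell between background and tissue, leaving WM inside), apply a
#'   second threshold within the tissue pixels to isolate the GM ribbon.
#' @return a binary [GMMask2D].
#' @export
otsuSegment <- function(img, tissueSide = c("auto", "bright", "dark"),
                        clean = FALSE, refineWithinTissue = FALSE) {
  tissueSide <- match.arg(tissueSide)
  th <- otsuThreshold(img@values)
  bright <- img@values > th$threshold
  side <- switch(tissueSide,
    bright = bright,
    dark = !bright,
    auto = {
      sb <- .ribbonScore(bright); sd <- .ribbonScore(!bright)
      if (sb == sd) {
        # degenerate scores: prefer the side that does not own the border
        bb <- mean(c(bright[1, ], bright[nrow(bright), ], bright[, 1],
                     bright[, ncol(bright)]))
        if (bb <= 0.5) bright else !bright
      } else if (sb > sd) bright else !bright
    })
  if (refineWithinTissue && .discLike(side) &&
      length(unique(img@values[side])) >= 2) {
    # the first threshold may have separated background from tissue (solid
    # disc, WM still inside); re-threshold within the tissue and accept
    # the refinement only if it exposes a ring (true GM-only caps stay)
    th2 <- otsuThreshold(img@values[side])
    refined <- side & img@values > th2$threshold
    if (any(refined) && !.discLike(refined)) side <- refined
  }
  if (clean) side <- .cleanMask2(side)
  GMMask2D(1 * side, spacing = img@spacing, origin = img@origin)
}

# TRUE when the largest component is disc-like: filling its holes barely
# changes its area (a cortical ribbon roughly doubles or more)
.discLike <- function(mask, ratio = 1.3) {
  if (!any(mask)) return(FALSE)
  labm <- EBImage::bwlabel(EBImage::as.Image(1 * mask))
  tab <- tabulate(as.integer(labm))
  comp <- EBImage::imageData(labm) == which.max(tab)
  filled <- EBImage::imageData(EBImage::fillHull(
    EBImage::as.Image(1 * comp))) > 0
  sum(filled) / sum(comp) < ratio
}

.cleanMask2 <- function(mask, maxHolePx = 16L) {
  if (!any(mask)) return(mask)
  labm <- EBImage::bwlabel(EBImage::as.Image(1 * mask))
  tab <- tabulate(as.integer(labm))
  comp <- EBImage::imageData(labm) == which.max(tab)
  # fill only small (noise) holes; large enclosed regions such as the WM
  # interior of a cortical ribbon must stay open
  filled <- EBImage::imageData(EBImage::fillHull(
    EBImage::as.Image(1 * comp))) > 0
  holes <- filled & !comp
  if (any(holes)) {
    hl <- EBImage::bwlabel(EBImage::as.Image(1 * holes))
    hm <- EBImage::imageData(hl)
    sizes <- tabulate(as.integer(hl))
    small <- which(sizes <= maxHolePx)
    comp <- comp | (hm %in% small & holes)
  }
  comp
}

#' The bundled classical segmenter (Otsu + largest-component cleanup)
#' @param tissueSide passed to [otsuSegment()].
#' @return a [Segmenter].
#' @export
otsuSegmenter <- function(tissueSide = "auto")
  Segmenter("otsu", function(img)
    otsuSegment(img, tissueSide = tissueSide, clean = TRUE,
                refineWithinTissue = TRUE))

#' Segment every section of a stack with fallback
#'
#' Runs the primary segmenter on each QC-passing section; when it returns
#' an empty mask the fallback (Otsu by default) is used and the event
#' logged. Sections where both produce an empty mask are flagged
#' `qc_fail`.
#'
#' @param stack a [SectionStack].
#' @param images named list of [Image2D]s keyed by the stack's `image`
#'   refs (or NULL to read from disk relative to `root`).
#' @param segmenter primary [Segmenter].
#' @param fallback fallback [Segmenter].
#' @param root directory for on-disk image refs.
#' @return list `masks` (named list of [GMMask2D]), `stack` (with
#'   qc_pass updated), `log` (data.frame: section key, segmenter used).
#' @export
segmentStack <- function(stack, images = NULL, segmenter = otsuSegmenter(),
                         fallback = otsuSegmenter(), root = ".") {
  rec <- stack@records
  masks <- list(); used <- character(nrow(rec)); keys <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    key <- rec$image[i]
    keys[i] <- key
    img <- if (!is.null(images)) images[[key]]
           else readSectionImage(file.path(root, key), rec$pixel_size_um[i])
    m <- tryCatch(segmenterPredict(segmenter, img), error = function(e) NULL)
    if (is.null(m) || sum(m@values) == 0) {
      m2 <- tryCatch(segmenterPredict(fallback, img),
                     error = function(e) NULL)
      if (is.null(m2) || sum(m2@values) == 0) {
        rec$qc_pass[i] <- FALSE
        rec$exclude_reason[i] <- "empty_segmentation"
        used[i] <- "none"
        next
      }
      masks[[key]] <- m2
      used[i] <- paste0("fallback:", fallback@name)
    } else {
      masks[[key]] <- m
      used[i] <- segmenter@name
    }
  }
  out <- SectionStack(rec, axis = stack@axis, speciesTag = stack@speciesTag)
  list(masks = masks, stack = out,
       log = data.frame(section = keys, segmenter = used))
}

#' Evaluate segmentations against manual masks
#'
#' @param preds,manuals paired lists of binary [GMMask2D]s (same names or
#'   order).
#' @param downsampleTo optional c(rows, cols): both masks are resampled
#'   (nearest) to this common size before Dice, mirroring validation
#'   protocols that score at a fixed working size.
#' @return list `perSection` (data.frame of Dice), `mean`, `sd`.
#' @export
evaluateSegmentation <- function(preds, manuals, downsampleTo = NULL) {
  if (length(preds) != length(manuals))
    stop("evaluateSegmentation: unpaired inputs")
  n <- length(preds)
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- preds[[i]]; m <- manuals[[i]]
    if (!is.null(downsampleTo)) {
      p <- .resizeMaskNearest(p, downsampleTo)
      m <- .resizeMaskNearest(m, downsampleTo)
    }
    d[i] <- dice(p, m)
  }
  list(perSection = data.frame(index = seq_len(n), dice = d),
       mean = mean(d), sd = stats::sd(d))
}

.resizeMaskNearest <- function(mask, dims) {
  d <- dim(mask@values)
  ri <- seq(1, d[1], length.out = dims[1])
  ci <- seq(1, d[2], length.out = dims[2])
  g <- expand.grid(r = ri, c = ci)
  GMMask2D(matrix(.nearest2(mask@values, g$r, g$c), dims[1], dims[2]),
           spacing = mask@spacing * (d - 1) / pmax(dims - 1, 1),
           origin = mask@origin)
}
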