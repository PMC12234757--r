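# Validation statistics: windowed and inter-section Dice, patch-based
# surface-interpolation validation, superpixel ROI parcellation and
# intensity-accuracy, regional regression, SUVR normalisation, and the
# permutation correlation test.

# 2D box sum of window w x w at all full-window positions, via integral
# image
.boxSum2 <- function(m, w) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  pad[-1, -1] <- cs
  nr <- nrow(m) - w + 1; nc <- ncol(m) - w + 1
  pad[(1 + w):(nrow(m) + 1), (1 + w):(ncol(m) + 1)] -
    pad[1:nr, (1 + w):(ncol(m) + 1)] -
    pad[(1 + w):(nrow(m) + 1), 1:nc] +
    pad[1:nr, 1:nc]
}

#' Windowed Dice between a predicted and a reference mask
#'
#' Dice is computed in every dense `window x window` position (stride 1)
#' and averaged, skipping windows with no predicted tissue, so missing or
#' damaged tissue does not penalise the score where nothing remains to
#' align.
#'
#' @param pred,ref binary [GMMask2D]s (or 0/1 matrices) on the same grid.
#' @param window window side in pixels (default 5).
#' @return mean of the local Dice scores.
#' @export
windowedDice <- function(pred, ref, window = 5L) {
  p <- if (is(pred, "GMMask2D")) pred@values else as.matrix(pred)
  r <- if (is(ref, "GMMask2D")) ref@values else as.matrix(ref)
  if (!identical(dim(p), dim(r))) stop("windowedDice: grid mismatch")
  p <- 1 * (p > 0.5); r <- 1 * (r > 0.5)
  if (sum(p) == 0) stop("windowedDice: no tissue in the predicted mask")
  pc <- .boxSum2(p, window)
  rc <- .boxSum2(r, window)
  ic <- .boxSum2(p * r, window)
  keep <- pc > 0
  if (!any(keep)) stop("windowedDice: no tissue-bearing window")
  num <- 2 * ic[keep]
  den <- pc[keep] + rc[keep]
  mean(num / den)
}

#' Inter-section Dice along the cutting axis
#'
#' Per section, the Dice with its nearest acquired anterior neighbour and
#' nearest acquired posterior neighbour are averaged (single-sided at the
#' ends of a slab).
#'
#' @param masks list of aligned binary [GMMask2D]s in axis order.
#' @param samples numeric positions along the axis (same order); default
#'   the list order.
#' @return numeric vector of per-section scores.
#' @export
intersectionDice <- function(masks, samples = seq_along(masks)) {
  n <- length(masks)
  if (n < 2) stop("intersectionDice: need at least 2 sections")
  ord <- order(samples)
  masks <- masks[ord]
  vapply(seq_len(n), function(i) {
    ds <- c(if (i > 1) dice(masks[[i]], masks[[i - 1]]),
            if (i < n) dice(masks[[i]], masks[[i + 1]]))
    mean(ds)
  }, numeric(1))[order(ord)]
}

# ---- patch-based surface-interpolation validation ----------------------

#' Specification of the patch validation draws
#' @param nSeeds number of seed vertices.
#' @param ringRange integer range of the known-ring distance n (hops).
#' @param coreRange integer range of the core-patch radius m (hops,
#'   truncated to m < n).
#' @param distanceWindowMm accepted range of mean seed-to-ring distance
#'   (mm, measured on the distance mesh); seeds outside are redrawn.
#' @param seed RNG seed.
#' @return a validated spec list.
#' @export
patchSpec <- function(nSeeds = 10000L, ringRange = c(2L, 6L),
                      coreRange = c(1L, 5L),
                      distanceWindowMm = c(0.05, 1.2), seed = 0L) {
  stopifnot(coreRange[1] >= 1, ringRange[1] >= 2,
            coreRange[1] < ringRange[2])
  list(nSeeds = as.integer(nSeeds), ringRange = as.integer(ringRange),
       coreRange = as.integer(coreRange),
       distanceWindowMm = distanceWindowMm, seed = as.integer(seed))
}

# hop rings within the subgraph of known vertices
.hopRings <- function(adj, known, seedV, nMax) {
  rings <- vector("list", nMax + 1)
  rings[[1]] <- seedV
  visited <- c(seedV)
  frontier <- seedV
  for (k in seq_len(nMax)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[known[nb]]
    nb <- setdiff(nb, visited)
    if (!length(nb)) return(NULL)
    rings[[k + 1]] <- nb
    visited <- c(visited, nb)
    frontier <- nb
  }
  rings
}

#' Patch-based validation of the surface interpolation
#'
#' Seed vertices are drawn at random among vertices with known values
#' (vertices intersecting acquired sections). For each seed, the `n`-hop
#' ring (n ~ U{ringRange}) within the known subgraph is treated as the
#' only known data, the vertices from the seed out to ring `n - 1` are
#' treated as missing, and the mean value of the core patch (seed out to
#' ring `m`, m ~ U{coreRange}, m < n) is estimated by spherical
#' interpolation from the ring and compared with its true mean. Seeds
#' whose mean seed-to-ring distance falls outside the physical window are
#' rejected and redrawn.
#'
#' @param sphereMesh sphere-space [SurfaceMesh] (vertex order matches the
#'   field).
#' @param field [VertexField] with known values on acquired vertices.
#' @param spec a [patchSpec()].
#' @param distanceMesh mesh used for physical distances (default
#'   `sphereMesh`; pass the native-space mesh for mm units).
#' @return list `trueMeans`, `estMeans`, `r2` (NA with `exactMatch` TRUE
#'   for a zero-variance field), `nAccepted`, `nRejected`.
#' @export
patchInterpolationValidation <- function(sphereMesh, field,
                                         spec = patchSpec(),
                                         distanceMesh = sphereMesh) {
  known <- field@known
  if (sum(known) < 20)
    stop("patchInterpolationValidation: insufficient known vertices")
  adj <- meshAdjacency(sphereMesh)
  knownIdx <- which(known)
  S <- sphereMesh@vertices / sqrt(rowSums(sphereMesh@vertices^2))
  withr::with_seed(spec$seed, {
    trueM <- numeric(0); estM <- numeric(0)
    rejected <- 0L; attempts <- 0L
    maxAttempts <- spec$nSeeds * 20L
    while (length(trueM) < spec$nSeeds && attempts < maxAttempts) {
      attempts <- attempts + 1L
      seedV <- knownIdx[sample.int(length(knownIdx), 1)]
      n <- sample(seq(spec$ringRange[1], spec$ringRange[2]), 1)
      mHi <- min(spec$coreRange[2], n - 1L)
      m <- sample(seq(spec$coreRange[1], mHi), 1)
      rings <- .hopRings(adj, known, seedV, n)
      if (is.null(rings)) { rejected <- rejected + 1L; next }
      ringN <- rings[[n + 1]]
      core <- unlist(rings[seq_len(m + 1)], use.names = FALSE)
      if (length(ringN) < 3) { rejected <- rejected + 1L; next }
      dv <- distanceMesh@vertices
      dists <- sqrt(rowSums((dv[ringN, , drop = FALSE] -
        matrix(dv[seedV, ], length(ringN), 3, byrow = TRUE))^2))
      md <- mean(dists)
      if (md < spec$distanceWindowMm[1] || md > spec$distanceWindowMm[2]) {
        rejected <- rejected + 1L; next
      }
      P <- S[ringN, , drop = FALSE]
      tris <- tryCatch(sphereTriangulation(P), error = function(e) NULL)
      if (is.null(tris)) { rejected <- rejected + 1L; next }
      w <- .sphereBary(S[core, , drop = FALSE], P, tris)
      vals <- field@values[ringN]
      est <- w$w1 * vals[w$t[, 1]] + w$w2 * vals[w$t[, 2]] +
        w$w3 * vals[w$t[, 3]]
      trueM <- c(trueM, mean(field@values[core]))
      estM <- c(estM, mean(est))
    }
    if (stats::var(trueM) < 1e-12) {
      r2 <- NA_real_
      exact <- max(abs(trueM - estM)) < 1e-8
    } else {
      r2 <- stats::cor(trueM, estM)^2
      exact <- FALSE
    }
    list(trueMeans = trueM, estMeans = estM, r2 = r2, exactMatch = exact,
         nAccepted = length(trueM), nRejected = rejected)
  })
}

# ---- ROI parcellation and intensity accuracy ---------------------------

#' Superpixel-style ROI parcellation of a section
#'
#' K-means over (position, intensity) with SLIC-style feature scaling; the
#' number of clusters targets `tissue area / targetMeanAreaMm2`. Clusters
#' are split into connected components, and fragments below a quarter of
#' the target area are merged into their largest neighbour, so every ROI
#' is contiguous. Background keeps label 0.
#'
#' @param section an [Image2D].
#' @param mask binary [GMMask2D] marking tissue.
#' @param targetMeanAreaMm2 target mean ROI area (mm^2).
#' @param compactness spatial-vs-intensity weighting (larger = more
#'   compact, more contiguous regions).
#' @param seed RNG seed for the k-means initialisation.
#' @return an [Image2D] of integer ROI labels (0 = background).
#' @export
makeRoiParcellation <- function(section, mask, targetMeanAreaMm2 = 21,
                                compactness = 4, seed = 0L) {
  sel <- which(mask@values > 0.5, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("makeRoiParcellation: empty mask")
  pxArea <- prod(section@spacing)
  areaMm2 <- nrow(sel) * pxArea
  k <- max(1L, as.integer(round(areaMm2 / targetMeanAreaMm2)))
  lab <- matrix(0L, nrow(section@values), ncol(section@values))
  if (k == 1 || nrow(sel) <= k) {
    lab[sel] <- 1L
    return(Image2D(lab, spacing = section@spacing,
                   origin = section@origin))
  }
  S <- sqrt(nrow(sel) / k)
  ints <- section@values[sel]
  si <- stats::sd(ints); if (!is.finite(si) || si == 0) si <- 1
  feat <- cbind(sel[, 1] / S * compactness, sel[, 2] / S * compactness,
                ints / si)
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(feat, centers = k, iter.max = 50, nstart = 1))
  lab[sel] <- km$cluster
  # enforce contiguity: connected components per cluster
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (cl in seq_len(k)) {
    comp <- EBImage::bwlabel(EBImage::as.Image(1 * (lab == cl)))
    cm <- EBImage::imageData(comp)
    for (cc in seq_len(max(cm))) {
      sel2 <- cm == cc
      if (!any(sel2)) next
      nxt <- nxt + 1L
      out[sel2] <- nxt
    }
  }
  # merge small fragments into their dominant neighbour
  minPx <- max(1, round(targetMeanAreaMm2 / pxArea / 4))
  sizes <- tabulate(out[out > 0])
  for (fr in which(sizes < minPx)) {
    sel2 <- out == fr
    nb <- integer(0)
    for (ax in 1:2) for (by in c(-1L, 1L))
      nb <- c(nb, .shiftAxis(out, ax, by)[sel2])
    nb <- nb[nb > 0 & nb != fr]
    if (length(nb)) out[sel2] <- as.integer(names(which.max(table(nb))))
  }
  # compact label ids
  ids <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], ids)
  Image2D(out, spacing = section@spacing, origin = section@origin)
}

#' Intensity accuracy of the reconstruction per ROI
#'
#' For one section: ROI means are measured on the raw section (truth), on
#' the 2D-transformed section (after the section's transform chain), and
#' on the reconstructed 3D volume under the identically transformed
#' parcellation; accuracy is `1 - |true - est| / true`. ROIs with zero
#' true mean are excluded.
#'
#' @param section raw [Image2D].
#' @param parcellation ROI label [Image2D] on the section grid (from
#'   [makeRoiParcellation()]).
#' @param chain the section's [TransformChain].
#' @param outGrid in-plane grid of the reconstruction (list
#'   dim/spacing/origin).
#' @param reconVolume reconstructed per-acquisition [Volume3D] (or NULL to
#'   skip the 3D stage).
#' @param worldY cutting-axis world coordinate of the section (mm).
#' @param mapToVolume optional function mapping n x 3 points from the
#'   section's (slab) space into the volume's space — the slab-to-
#'   reference pull-back when the reconstruction lives on the reference
#'   grid. Default: identity.
#' @return data.frame (roi, true, est2d, acc2d, est3d, acc3d).
#' @export
roiAccuracy <- function(section, parcellation, chain, outGrid,
                        reconVolume = NULL, worldY = NA_real_,
                        mapToVolume = NULL) {
  warped <- applyTransform2D(section, chain, outGrid = outGrid,
                             mode = "linear")
  parcW <- applyTransform2D(parcellation, chain, outGrid = outGrid,
                            mode = "nearest")
  labs <- sort(unique(as.integer(parcellation@values)))
  labs <- labs[labs > 0]
  rows <- lapply(labs, function(l) {
    true <- mean(section@values[parcellation@values == l])
    if (!is.finite(true) || true == 0) return(NULL)
    selW <- parcW@values == l
    if (!any(selW)) return(NULL)
    est2 <- mean(warped@values[selW])
    acc2 <- 1 - abs(true - est2) / true
    est3 <- acc3 <- NA_real_
    if (!is.null(reconVolume)) {
      idx <- which(selW, arr.ind = TRUE)
      pts <- cbind(
        .indexToWorld(idx[, 1], outGrid$origin[1], outGrid$spacing[1]),
        rep(worldY, nrow(idx)),
        .indexToWorld(idx[, 2], outGrid$origin[2], outGrid$spacing[2]))
      if (!is.null(mapToVolume)) pts <- mapToVolume(pts)
      est3 <- mean(sampleAt(reconVolume, pts, mode = "linear"))
      acc3 <- 1 - abs(true - est3) / true
    }
    data.frame(roi = l, true = true, est2d = est2, acc2d = acc2,
               est3d = est3, acc3d = acc3)
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares regression between paired regional means
#' @param meansA,meansB paired numeric vectors (>= 3 regions).
#' @return list `slope`, `intercept`, `r2` (of B regressed on A).
#' @export
regionalRegression <- function(meansA, meansB) {
  if (length(meansA) != length(meansB) || length(meansA) < 3)
    stop("regionalRegression: need >= 3 paired regions")
  if (stats::var(meansA) == 0)
    stop("regionalRegression: zero variance in the predictor")
  fit <- stats::lm(meansB ~ meansA)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2)
}

#' SUVR normalisation of a PET volume
#'
#' Divides the volume by the mean value inside the WM mask.
#'
#' @param pet a [Volume3D].
#' @param wmMask binary [GMMask3D]-style mask on the same grid.
#' @return the normalised [Volume3D].
#' @export
suvr <- function(pet, wmMask) {
  if (!identical(dim(pet@values), dim(wmMask@values)))
    stop("suvr: grid mismatch")
  wmMean <- mean(pet@values[wmMask@values > 0.5])
  if (!is.finite(wmMean) || wmMean == 0)
    stop("suvr: WM mean is zero")
  Volume3D(pet@values / wmMean, spacing = pet@spacing, origin = pet@origin,
           cutAxis = pet@cutAxis)
}

#' Permutation test for a difference in mean correlation
#'
#' Observed statistic: |mean(within) - mean(between)|. The null is built
#' by randomly permuting group labels over the pooled correlations;
#' p = (1 + #{permuted >= observed}) / (nPerm + 1).
#'
#' @param withinGroup,betweenGroup numeric vectors of correlations.
#' @param nPerm number of permutations (values below 100 warn).
#' @param seed RNG seed.
#' @return list `p`, `observed`, `nPerm`.
#' @export
permutationCorrTest <- function(withinGroup, betweenGroup, nPerm = 10000L,
                                seed = 0L) {
  stopifnot(length(withinGroup) >= 1, length(betweenGroup) >= 1)
  if (nPerm < 100) warning("permutationCorrTest: nPerm < 100")
  obs <- abs(mean(withinGroup) - mean(betweenGroup))
  pooled <- c(withinGroup, betweenGroup)
  n1 <- length(withinGroup)
  stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(i) {
      idx <- sample.int(length(pooled), n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
  })
  list(p = (1 + sum(stats >= obs - 1e-15)) / (nPerm + 1), observed = obs,
       nPerm = nPerm)
}
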