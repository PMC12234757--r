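# Stage 2: iterative multi-resolution alignment. At each resolution of the
# schedule the 2D GM masks are assembled (through their best available
# transforms) into a continuous fuzzy GM volume, the reference GM is
# 3D-registered to it, and every section is refined in 2D against its
# corresponding reference plane; the refined fields become the best
# available transforms of the next, finer resolution.

#' MultiresState: the state of the multi-resolution alignment
#'
#' @slot schedule the resolution schedule used (mm, strictly decreasing).
#' @slot chains named list (by image ref) of [TransformChain]s after the
#'   final resolution.
#' @slot registrations per-slab list: the [register3D()] result of the
#'   final resolution (affine, field, pullback, aligned reference).
#' @slot reconGM per-slab reconstructed fuzzy [GMMask3D] at the final
#'   resolution.
#' @slot diceLog data.frame (slab, resolutionMm, section, dice) after each
#'   2D refinement pass.
#' @export
setClass("MultiresState",
  representation(schedule = "numeric", chains = "list",
                 registrations = "list", reconGM = "list",
                 diceLog = "data.frame"))

setMethod("show", "MultiresState", function(object) {
  med <- stats::aggregate(dice ~ resolutionMm, object@diceLog, stats::median)
  cat("MultiresState:", length(object@chains), "sections,",
      length(object@reconGM), "slab(s)\n")
  cat("  median section-to-reference Dice by resolution:\n")
  for (i in seq_len(nrow(med)))
    cat(sprintf("    %.2g mm: %.3f\n", med$resolutionMm[i], med$dice[i]))
})

#' Validate a resolution schedule
#' @param resolutionsMm numeric vector of resolutions (mm).
#' @return the schedule, or an error if not strictly decreasing/positive.
#' @export
resolutionSchedule <- function(resolutionsMm) {
  if (any(resolutionsMm <= 0) || any(diff(resolutionsMm) >= 0))
    stop("resolution schedule must be strictly decreasing and positive")
  resolutionsMm
}

#' Assemble a continuous fuzzy GM volume from aligned 2D masks
#'
#' Each acquired mask is resampled through its transform chain onto a
#' common in-plane grid, stacked at its plane, and the gaps along the
#' cutting axis are filled by linear interpolation between the two nearest
#' acquired planes (inverse-distance weights); planes outside the acquired
#' range stay background. The result is then downsampled to the requested
#' isotropic resolution.
#'
#' @param stack a [SectionStack] (one slab).
#' @param masks named list of [GMMask2D]s keyed by image ref.
#' @param chains named list of [TransformChain]s keyed by image ref.
#' @param resMm output isotropic resolution (mm).
#' @param grid optional in-plane grid override (list dim/spacing/origin at
#'   `resMm`).
#' @return a fuzzy [GMMask3D] at `resMm`.
#' @export
assembleGMVolume <- function(stack, masks, chains, resMm, grid = NULL) {
  rec <- stack@records[stack@records$qc_pass, ]
  if (nrow(rec) < 2) stop("assembleGMVolume: need at least 2 planes")
  if (is.null(grid)) grid <- commonInPlaneGrid(masks[rec$image], resMm)
  thick <- rec$section_thickness_um[1] / 1000
  samples <- rec$sample
  planeIdx <- samples - min(samples) + 1L
  nPlane <- max(planeIdx)
  arr <- array(0, c(grid$dim[1], nPlane, grid$dim[2]))
  for (i in seq_len(nrow(rec))) {
    key <- rec$image[i]
    ch <- chains[[key]] %||% TransformChain()
    m <- applyTransform2D(masks[[key]], ch,
                          outGrid = list(dim = grid$dim,
                                         spacing = grid$spacing,
                                         origin = grid$origin),
                          mode = "linear")
    arr[, planeIdx[i], ] <- m@values
  }
  acquired <- sort(unique(planeIdx))
  if (length(acquired) >= 2) {
    for (j in seq_len(nPlane)) {
      if (j %in% acquired) next
      lo <- acquired[acquired < j]; hi <- acquired[acquired > j]
      if (!length(lo) || !length(hi)) next  # outside acquired range
      a <- max(lo); b <- min(hi)
      w <- (b - j) / (b - a)
      arr[, j, ] <- w * arr[, a, ] + (1 - w) * arr[, b, ]
    }
  }
  origin <- c(grid$origin[1], min(samples) * thick, grid$origin[2])
  vol <- GMMask3D(pmin(pmax(arr, 0), 1),
                  spacing = c(resMm, thick, resMm), origin = origin,
                  isBinary = FALSE)
  resampleVolume(vol, resMm, mode = "linear")
}

#' Extract the reference slab between manual bounds
#'
#' Crops the reference volume along the cutting axis to the world interval
#' `[posteriorMm, anteriorMm]`, preserving the world origin of the kept
#' region.
#'
#' @param refGM reference [GMMask3D]/[Volume3D].
#' @param bounds list/row with `anteriorMm` > `posteriorMm` (mm, world
#'   coordinates along the cutting axis).
#' @return the cropped volume.
#' @export
extractReferenceSlab <- function(refGM, bounds) {
  if (bounds$anteriorMm <= bounds$posteriorMm)
    stop("extractReferenceSlab: empty interval")
  ax <- refGM@cutAxis
  n <- dim(refGM@values)[ax]
  w <- .indexToWorld(seq_len(n), refGM@origin[ax], refGM@spacing[ax])
  keep <- which(w >= bounds$posteriorMm & w <= bounds$anteriorMm)
  if (!length(keep))
    stop("extractReferenceSlab: bounds outside the reference extent")
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[ax]] <- keep
  arr <- do.call(`[`, c(list(refGM@values), idx, list(drop = FALSE)))
  origin <- refGM@origin
  origin[ax] <- w[keep[1]]
  if (is(refGM, "GMMask3D"))
    GMMask3D(arr, spacing = refGM@spacing, origin = origin,
             cutAxis = ax, isBinary = refGM@isBinary)
  else Volume3D(arr, spacing = refGM@spacing, origin = origin, cutAxis = ax)
}

#' Run the multi-resolution 3D/2D alignment loop
#'
#' For every resolution of the schedule, per slab: assemble the fuzzy GM
#' volume with the best available transforms (the stage-1 rigids at the
#' first resolution, the refined chains afterwards), register the
#' reference slab to it in 3D (affine + deformable on the GM pair), and
#' refine every section in 2D against its corresponding plane of the
#' aligned reference (nearest plane along the cutting axis, ties toward
#' posterior). The 2D fields accumulate on the chains across resolutions.
#'
#' @param stack a [SectionStack] (any number of slabs).
#' @param masks named list of binary [GMMask2D]s keyed by image ref.
#' @param refGM the reference GM volume ([GMMask3D], binary or fuzzy).
#' @param rigids stage-1 rigid transforms (named by image ref).
#' @param schedule strictly decreasing resolutions in mm (e.g.
#'   `c(4, 2, 1)`).
#' @param boundsPerSlab data.frame (slab, anteriorMm, posteriorMm) of
#'   manual slab bounds; NULL uses the full reference for every slab
#'   (single-slab datasets).
#' @param demonsIters3D,demonsIters2D deformable iteration budgets.
#' @return a [MultiresState].
#' @export
runMultires <- function(stack, masks, refGM, rigids,
                        schedule = c(4, 2, 1), boundsPerSlab = NULL,
                        demonsIters3D = 30L, demonsIters2D = 40L) {
  schedule <- resolutionSchedule(schedule)
  recAll <- stack@records[stack@records$qc_pass, ]
  slabs <- sort(unique(recAll$slab))
  chains <- stats::setNames(
    lapply(recAll$image, function(k)
      TransformChain(rigid = rigids[[k]] %||% Rigid2D())),
    recAll$image)
  regs <- list(); recons <- list()
  logRows <- list()

  for (s in slabs) {
    rec <- recAll[recAll$slab == s, , drop = FALSE]
    sub <- SectionStack(rec, axis = stack@axis, speciesTag = stack@speciesTag)
    bounds <- if (!is.null(boundsPerSlab)) {
      b <- boundsPerSlab[boundsPerSlab$slab == s, , drop = FALSE]
      if (nrow(b) == 0) stop("runMultires: no bounds for slab ", s)
      list(anteriorMm = b$anteriorMm[1], posteriorMm = b$posteriorMm[1])
    } else NULL
    refSlabFull <- if (is.null(bounds)) refGM
                   else extractReferenceSlab(refGM, bounds)

    for (res in schedule) {
      recon <- assembleGMVolume(sub, masks, chains, res)
      refSlab <- resampleVolume(refSlabFull, res, mode = "linear")
      reg <- register3D(refSlab, recon, demonsIters = demonsIters3D)
      refAligned <- reg$aligned
      thick <- rec$section_thickness_um[1] / 1000
      inGrid <- list(dim = dim(recon@values)[c(1, 3)],
                     spacing = recon@spacing[c(1, 3)],
                     origin = recon@origin[c(1, 3)])
      for (i in seq_len(nrow(rec))) {
        key <- rec$image[i]
        wy <- rec$sample[i] * thick
        jf <- .worldToIndex(wy, recon@origin[2], recon@spacing[2])
        j <- min(max(1L, as.integer(floor(jf + 0.5))),
                 dim(recon@values)[2])   # ties toward posterior (lower j)
        secMask <- applyTransform2D(masks[[key]], chains[[key]],
                                    outGrid = inGrid, mode = "linear")
        refPlane <- extractPlane(refAligned, j)
        fld <- refine2D(secMask, refPlane, iters = demonsIters2D)
        chains[[key]]@warps <- c(chains[[key]]@warps, list(fld))
        logRows[[length(logRows) + 1L]] <- data.frame(
          slab = s, resolutionMm = res, section = key,
          dice = attr(fld, "dice"), flagged = attr(fld, "flagged"))
      }
      regs[[as.character(s)]] <- reg
      recons[[as.character(s)]] <- recon
    }
    # final assembly with the fully refined chains, for downstream stages
    recons[[as.character(s)]] <-
      assembleGMVolume(sub, masks, chains, schedule[length(schedule)])
  }
  new("MultiresState", schedule = schedule, chains = chains,
      registrations = regs, reconGM = recons,
      diceLog = do.call(rbind, logRows))
}
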