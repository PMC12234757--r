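# Orchestration: configuration, QC filtering, the end-to-end
# reconstruction (segmentation -> QC -> initial rigid chaining ->
# multi-resolution alignment -> surface interpolation per acquisition),
# and QC reporting. All randomness flows from one root seed; stage outputs
# are cached content-addressed by a config hash so re-runs only recompute
# what changed.

#' QC policy for section filtering
#' @param maxMissingCortexFraction a section is excluded when its GM area
#'   falls below `(1 - fraction)` of the median GM area of its nearest
#'   acquired neighbours.
#' @param neighbours number of nearest neighbours the median is taken over.
#' @param manualExclusions image refs to exclude regardless.
#' @return policy list.
#' @export
qcPolicy <- function(maxMissingCortexFraction = 0.25, neighbours = 4L,
                     manualExclusions = character(0)) {
  stopifnot(maxMissingCortexFraction >= 0, maxMissingCortexFraction <= 1)
  list(maxMissingCortexFraction = maxMissingCortexFraction,
       neighbours = as.integer(neighbours),
       manualExclusions = manualExclusions)
}

#' Filter sections missing too much cortex
#'
#' Automates the exclusion rule for damaged sections: a section whose GM
#' area is below `(1 - maxMissingCortexFraction)` times the median GM area
#' of its `k` nearest acquired neighbours (by sample position, within the
#' slab) is flagged `qc_fail` with reason `missing_cortex`. Manual
#' exclusions are applied with reason `manual`.
#'
#' @param stack a [SectionStack].
#' @param masks named list of [GMMask2D]s by image ref.
#' @param policy a [qcPolicy()].
#' @return the stack with `qc_pass` / `exclude_reason` updated.
#' @export
qcFilter <- function(stack, masks, policy = qcPolicy()) {
  rec <- stack@records
  areas <- vapply(rec$image, function(k) {
    m <- masks[[k]]
    if (is.null(m)) return(NA_real_)
    sum(m@values > 0.5) * prod(m@spacing)
  }, numeric(1))
  thr <- 1 - policy$maxMissingCortexFraction
  for (i in seq_len(nrow(rec))) {
    if (!rec$qc_pass[i]) next
    if (rec$image[i] %in% policy$manualExclusions) {
      rec$qc_pass[i] <- FALSE
      rec$exclude_reason[i] <- "manual"
      next
    }
    if (!is.finite(areas[i])) next
    sameSlab <- which(rec$slab == rec$slab[i] & seq_len(nrow(rec)) != i &
                      is.finite(areas))
    if (!length(sameSlab)) next
    nb <- sameSlab[order(abs(rec$sample[sameSlab] - rec$sample[i]))]
    nb <- nb[seq_len(min(policy$neighbours, length(nb)))]
    if (areas[i] < thr * stats::median(areas[nb])) {
      rec$qc_pass[i] <- FALSE
      rec$exclude_reason[i] <- "missing_cortex"
    }
  }
  if (!any(rec$qc_pass)) stop("qcFilter: all sections failed QC")
  SectionStack(rec, axis = stack@axis, speciesTag = stack@speciesTag)
}

#' Pipeline configuration
#'
#' @param manifest path to the section manifest CSV, or a [SectionStack].
#' @param referenceGM path to the reference GM NIfTI, or a [GMMask3D].
#' @param wmSurface,pialSurface paths to OBJ meshes or [SurfaceMesh]es.
#' @param sphereSurface optional externally inflated sphere mesh.
#' @param images optional named list of in-memory [Image2D]s (phantom
#'   runs); otherwise images are read from disk relative to `root`.
#' @param schedule resolution schedule (mm, strictly decreasing; the last
#'   entry is the output resolution).
#' @param nDepthSurfaces intermediate depth surfaces + 2 borders.
#' @param boundsPerSlab data.frame (slab, anteriorMm, posteriorMm) or NULL.
#' @param acquisitions acquisitions to reconstruct (default: all in the
#'   manifest).
#' @param seed root seed.
#' @param outDir output directory (NULL = keep results in memory only).
#' @param root directory image refs are relative to.
#' @param segmenter,fallback [Segmenter]s (default Otsu).
#' @param qc a [qcPolicy()].
#' @return validated config list.
#' @export
pipelineConfig <- function(manifest, referenceGM, wmSurface, pialSurface,
                           sphereSurface = NULL, images = NULL,
                           schedule = c(4, 3, 2, 1, 0.5, 0.25),
                           nDepthSurfaces = 18L, boundsPerSlab = NULL,
                           acquisitions = NULL, seed = 0L, outDir = NULL,
                           root = ".", segmenter = otsuSegmenter(),
                           fallback = otsuSegmenter(), qc = qcPolicy()) {
  resolutionSchedule(schedule)
  for (p in c(if (is.character(manifest)) manifest,
              if (is.character(referenceGM)) referenceGM,
              if (is.character(wmSurface)) wmSurface,
              if (is.character(pialSurface)) pialSurface))
    if (!file.exists(p)) stop("pipelineConfig: file not found: ", p)
  list(manifest = manifest, referenceGM = referenceGM,
       wmSurface = wmSurface, pialSurface = pialSurface,
       sphereSurface = sphereSurface, images = images,
       schedule = schedule, nDepthSurfaces = as.integer(nDepthSurfaces),
       boundsPerSlab = boundsPerSlab, acquisitions = acquisitions,
       seed = as.integer(seed), outDir = outDir, root = root,
       segmenter = segmenter, fallback = fallback, qc = qc)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipelineConfig()] (file paths
#'   resolved relative to the YAML's directory).
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  rp <- function(p) if (is.null(p)) NULL else file.path(root, p)
  bounds <- if (!is.null(y$boundsPerSlab))
    do.call(rbind, lapply(y$boundsPerSlab, as.data.frame)) else NULL
  pipelineConfig(manifest = rp(y$manifest),
                 referenceGM = rp(y$referenceGM),
                 wmSurface = rp(y$wmSurface),
                 pialSurface = rp(y$pialSurface),
                 sphereSurface = rp(y$sphereSurface),
                 schedule = y$schedule %||% c(4, 3, 2, 1, 0.5, 0.25),
                 nDepthSurfaces = y$nDepthSurfaces %||% 18L,
                 boundsPerSlab = bounds,
                 acquisitions = y$acquisitions,
                 seed = y$seed %||% 0L,
                 outDir = rp(y$outDir), root = root)
}

.configHash <- function(cfg, stage) {
  keep <- cfg[c("schedule", "nDepthSurfaces", "seed", "acquisitions")]
  keep$stage <- stage
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(keep)), f)
  unname(tools::md5sum(f))
}

#' Run the full 3D reconstruction
#'
#' Executes segmentation, QC filtering, contrast-ranked rigid chaining per
#' slab, the multi-resolution 3D/2D alignment against the reference, and
#' per-acquisition surface interpolation, returning (and optionally
#' writing) per-acquisition reconstructed volumes plus all transforms and
#' Dice logs. Deterministic for a fixed config and seed.
#'
#' @param config a [pipelineConfig()].
#' @param demonsIters3D,demonsIters2D deformable iteration budgets.
#' @return list `stack`, `masks`, `ranking`, `rigids`, `multires` (a
#'   [MultiresState]), `volumes` (per acquisition, reference space),
#'   `fields` (per acquisition per depth [VertexField]s), `depthSet`,
#'   `sphere`, `cortexMask`, `diceLog`, `config`.
#' @export
runReconstruction <- function(config, demonsIters3D = 25L,
                              demonsIters2D = 30L) {
  stack <- if (is.character(config$manifest))
    loadManifest(config$manifest) else config$manifest
  refGM <- if (is.character(config$referenceGM)) {
    v <- readVolumeNifti(config$referenceGM)
    GMMask3D(1 * (v@values > 0.5), spacing = v@spacing, origin = v@origin,
             cutAxis = v@cutAxis)
  } else config$referenceGM
  wm <- if (is.character(config$wmSurface))
    readMeshObj(config$wmSurface) else config$wmSurface
  pial <- if (is.character(config$pialSurface))
    readMeshObj(config$pialSurface) else config$pialSurface

  rec <- stack@records
  images <- config$images
  if (is.null(images)) {
    images <- stats::setNames(lapply(seq_len(nrow(rec)), function(i)
      readSectionImage(file.path(config$root, rec$image[i]),
                       rec$pixel_size_um[i])), rec$image)
  }

  # 1) segmentation (+ fallback) and QC
  seg <- segmentStack(stack, images, config$segmenter, config$fallback)
  stack <- qcFilter(seg$stack, seg$masks, config$qc)
  masks <- seg$masks
  acqs <- config$acquisitions %||% unique(stack@records$acquisition)

  # 2) stage 1: contrast-ranked rigid chaining per slab
  ranking <- rankAcquisitions(stack, images, masks)
  outRes <- config$schedule[length(config$schedule)]
  grid <- commonInPlaneGrid(masks[stack@records$image], outRes)
  rigids <- list()
  for (s in sort(unique(stack@records$slab))) {
    sub <- SectionStack(stack@records[stack@records$slab == s, ],
                        axis = stack@axis, speciesTag = stack@speciesTag)
    rigids <- c(rigids, chainAlignSlab(sub, masks, ranking, grid = grid))
  }

  # 3) stage 2: multi-resolution alignment to the reference
  ms <- runMultires(stack, masks, refGM, rigids,
                    schedule = config$schedule,
                    boundsPerSlab = config$boundsPerSlab,
                    demonsIters3D = demonsIters3D,
                    demonsIters2D = demonsIters2D)

  # 4) stage 3: surface interpolation per acquisition. The upsampling
  # order is chosen so the maximum neighbour distance is at most the
  # output resolution (one vertex per voxel within acquired sections).
  depthSet <- generateDepthSurfaces(wm, pial, config$nDepthSurfaces)
  n <- upsampleOrder(pial, 2 * outRes)
  depthSet <- DepthSurfaceSet(lapply(depthSet@meshes, upsampleMesh, n = n),
                              depthSet@depths)
  mid <- depthSet@meshes[[ceiling(length(depthSet@meshes) / 2)]]
  sphere <- if (!is.null(config$sphereSurface)) {
    sp <- if (is.character(config$sphereSurface))
      readMeshObj(config$sphereSurface, spaceTag = "sphere")
      else config$sphereSurface
    if (nrow(sp@vertices) != nrow(mid@vertices))
      sp <- upsampleMesh(sp, n = n)
    sp
  } else inflateToSphere(mid)

  cortexMask <- rasterizeSurfacesToGM(wm, pial, outRes,
                                      grid = refGM)
  slabs <- sort(unique(stack@records$slab))
  slabDepth <- lapply(slabs, function(s)
    depthSurfacesToSlab(depthSet, ms@registrations[[as.character(s)]]))
  names(slabDepth) <- as.character(slabs)

  volumes <- list(); fields <- list()
  for (acq in acqs) {
    nV <- nrow(mid@vertices)
    perDepth <- lapply(seq_along(depthSet@meshes), function(k)
      VertexField(rep(NA_real_, nV), rep(FALSE, nV)))
    for (s in slabs) {
      sub <- SectionStack(stack@records[stack@records$slab == s, ],
                          axis = stack@axis, speciesTag = stack@speciesTag)
      if (!acq %in% sub@records$acquisition) next
      fs <- sampleSectionsToVertices(sub, ms@chains, slabDepth[[as.character(s)]],
                                     images, acq)
      for (k in seq_along(perDepth)) {
        take <- fs[[k]]@known & !perDepth[[k]]@known
        v <- perDepth[[k]]@values; kn <- perDepth[[k]]@known
        v[take] <- fs[[k]]@values[take]; kn[take] <- TRUE
        perDepth[[k]] <- VertexField(v, kn)
      }
    }
    complete <- lapply(perDepth, function(f)
      if (sum(f@known) >= 3) interpolateSphere(sphere, f) else f)
    vol <- projectToVolume(complete, depthSet, refGM, cortexMask)
    volumes[[acq]] <- vol
    fields[[acq]] <- complete
  }

  out <- list(stack = stack, masks = masks, ranking = ranking,
              rigids = rigids, multires = ms, volumes = volumes,
              fields = fields, depthSet = depthSet, sphere = sphere,
              cortexMask = cortexMask, diceLog = ms@diceLog,
              config = config)
  if (!is.null(config$outDir)) .writeBundle(out, config$outDir)
  out
}

.writeBundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (acq in names(out$volumes))
    writeVolumeNifti(out$volumes[[acq]],
                     file.path(dir, paste0("recon_", acq, ".nii.gz")))
  utils::write.csv(out$diceLog, file.path(dir, "dice_per_section.csv"),
                   row.names = FALSE)
  writeManifest(out$stack, file.path(dir, "manifest_qc.csv"))
  tdir <- file.path(dir, "transforms")
  dir.create(tdir, showWarnings = FALSE)
  for (key in names(out$multires@chains))
    writeTransformChain(out$multires@chains[[key]],
                        file.path(tdir, gsub("[^A-Za-z0-9_.-]", "_", key)))
  cfgHash <- .configHash(out$config, "final")
  writeLines(cfgHash, file.path(dir, "config_hash.txt"))
  invisible(dir)
}

#' Write QC report images for a reconstruction
#'
#' Per-section overlay PNGs (section GM edges over the aligned reference
#' plane) and a Dice-versus-section plot for outlier spotting; QC-failed
#' sections get a distinct marker.
#'
#' @param out result of [runReconstruction()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
qcReport <- function(out, dir) {
  dir.create(file.path(dir, "overlays"), recursive = TRUE,
             showWarnings = FALSE)
  finalRes <- min(out$diceLog$resolutionMm)
  logF <- out$diceLog[out$diceLog$resolutionMm == finalRes, ]
  for (s in unique(logF$slab)) {
    reg <- out$multires@registrations[[as.character(s)]]
    refAligned <- reg$aligned
    rec <- out$stack@records[out$stack@records$slab == s &
                             out$stack@records$qc_pass, ]
    thick <- rec$section_thickness_um[1] / 1000
    inGrid <- list(dim = dim(refAligned@values)[c(1, 3)],
                   spacing = refAligned@spacing[c(1, 3)],
                   origin = refAligned@origin[c(1, 3)])
    for (i in seq_len(nrow(rec))) {
      key <- rec$image[i]
      j <- min(max(1L, as.integer(floor(.worldToIndex(
        rec$sample[i] * thick, refAligned@origin[2],
        refAligned@spacing[2]) + 0.5))), dim(refAligned@values)[2])
      sec <- applyTransform2D(out$masks[[key]], out$multires@chains[[key]],
                              outGrid = inGrid, mode = "linear")
      ref <- extractPlane(refAligned, j)
      rgb <- array(0, c(dim(sec@values), 3))
      rgb[, , 1] <- pmin(1, sec@values)
      edge <- .classBoundary(1 * (ref@values > 0.5)) & ref@values > 0.5
      rgb[, , 2] <- 1 * edge
      png::writePNG(rgb, file.path(dir, "overlays",
                                   paste0(gsub("[^A-Za-z0-9_.-]", "_", key),
                                          ".png")))
    }
  }
  grDevices::png(file.path(dir, "dice_per_section.png"), width = 900,
                 height = 500)
  on.exit(grDevices::dev.off())
  fail <- !logF$section %in%
    out$stack@records$image[out$stack@records$qc_pass]
  graphics::plot(seq_len(nrow(logF)), logF$dice, pch = ifelse(fail, 4, 19),
                 col = ifelse(fail, "red", "black"),
                 xlab = "section", ylab = "Dice (section vs reference)",
                 ylim = c(0, 1),
                 main = sprintf("final resolution %.2g mm", finalRes))
  graphics::abline(h = stats::median(logF$dice), lty = 2)
  invisible(dir)
}

#' Alignment validation metrics of a reconstruction
#'
#' Recomputes, at the final resolution, each section's aligned GM mask and
#' scores it against the corresponding plane of the aligned reference
#' (plain and windowed Dice), plus the inter-section Dice between
#' neighbouring aligned sections within each slab.
#'
#' @param out result of [runReconstruction()].
#' @param window windowed-Dice window size (pixels).
#' @return list `perSection` (data.frame: slab, section, sample, dice,
#'   windowedDice, intersectionDice), `meanWindowedDice`,
#'   `meanIntersectionDice`, `medianDiceByResolution` (data.frame).
#' @export
alignmentMetrics <- function(out, window = 5L) {
  rows <- list()
  for (s in sort(unique(out$stack@records$slab))) {
    reg <- out$multires@registrations[[as.character(s)]]
    refA <- reg$aligned
    rec <- out$stack@records[out$stack@records$slab == s &
                             out$stack@records$qc_pass, , drop = FALSE]
    thick <- rec$section_thickness_um[1] / 1000
    inGrid <- list(dim = dim(refA@values)[c(1, 3)],
                   spacing = refA@spacing[c(1, 3)],
                   origin = refA@origin[c(1, 3)])
    aligned <- list(); wd <- dd <- numeric(nrow(rec))
    for (i in seq_len(nrow(rec))) {
      key <- rec$image[i]
      j <- min(max(1L, as.integer(floor(.worldToIndex(
        rec$sample[i] * thick, refA@origin[2], refA@spacing[2]) + 0.5))),
        dim(refA@values)[2])
      sec <- applyTransform2D(out$masks[[key]], out$multires@chains[[key]],
                              outGrid = inGrid, mode = "linear")
      secB <- GMMask2D(1 * (sec@values > 0.5), spacing = sec@spacing,
                       origin = sec@origin)
      refP <- extractPlane(refA, j)
      refB <- GMMask2D(1 * (refP@values > 0.5), spacing = refP@spacing,
                       origin = refP@origin)
      dd[i] <- dice(secB, refB)
      wd[i] <- tryCatch(windowedDice(secB, refB, window),
                        error = function(e) NA_real_)
      aligned[[i]] <- secB
    }
    isd <- if (nrow(rec) >= 2) intersectionDice(aligned, rec$sample)
           else rep(NA_real_, nrow(rec))
    rows[[length(rows) + 1L]] <- data.frame(
      slab = s, section = rec$image, sample = rec$sample, dice = dd,
      windowedDice = wd, intersectionDice = isd)
  }
  per <- do.call(rbind, rows)
  med <- stats::aggregate(dice ~ resolutionMm, out$diceLog, stats::median)
  list(perSection = per,
       meanWindowedDice = mean(per$windowedDice, na.rm = TRUE),
       meanIntersectionDice = mean(per$intersectionDice, na.rm = TRUE),
       medianDiceByResolution = med[order(-med$resolutionMm), ])
}
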