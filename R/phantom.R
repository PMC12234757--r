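# Synthetic ground-truth generator. The phantom brain is a star-shaped
# folded cortical ribbon: a radial pial surface R(u) = R0 + A f(u) around a
# fixed centre, with the WM-GM border at constant cortical thickness below
# it. Star shape means sphere inflation is exact radial projection, so
# surface-interpolation tests isolate interpolation error from inflation
# quality. Acquisition "densities" are analytic band-limited random fields,
# evaluable at voxels and mesh vertices alike, giving a known forward model
# for every downstream check.

# fold function on the unit sphere, deterministic in the fold parameters.
# Folds run in the in-plane angle about the cutting axis (y) with a fixed
# angular phase, and their amplitude is modulated smoothly (sin^2 of the
# polar angle), so coronal cross-sections share one fold orientation: the
# inter-section alignment then has a well-defined rigid ground truth.
.foldFun <- function(u, foldCount) {
  theta <- acos(pmin(pmax(u[, 2], -1), 1))
  phi <- atan2(u[, 3], u[, 1])
  (0.75 * sin(foldCount * phi) + 0.25 * cos((foldCount - 1) * phi)) *
    sin(theta)^2
}

.radialShape <- function(u, shape) {
  f <- if (shape$foldAmplitudeMm == 0) 0 else
    shape$foldAmplitudeMm * .foldFun(u, shape$foldCount)
  pial <- shape$radiusMm + f
  list(pial = pial, wm = pial - shape$thicknessMm)
}

#' Build a synthetic phantom brain
#'
#' Creates a labelled truth volume (0 background, 1 WM, 2 cortical GM) and
#' shared-topology WM/pial surface meshes generated by radial offsets of a
#' single base icosphere.
#'
#' @param shape list with `radiusMm` (base pial radius), `foldCount`,
#'   `foldAmplitudeMm`, `thicknessMm` (cortical thickness, > 0) and
#'   `elongationY` (stretch factor along the cutting axis; real brains are
#'   long relative to their cross-section, which keeps the anatomy change
#'   between neighbouring sections small).
#' @param dims integer(3) truth-volume array size. The default uses twice
#'   the sampling density along the cutting axis (axis 2) so that section
#'   thickness is half the in-plane voxel size, emulating sections much
#'   thinner than the reconstruction resolution.
#' @param spacingMm truth-volume voxel size, scalar or per-axis (mm).
#' @param baseSubdiv icosphere subdivision rounds for the base mesh.
#' @param seed integer seed recorded on the phantom (the shape itself is
#'   deterministic; the seed feeds the density fields and slicing).
#' @return a [Phantom].
#' @export
makePhantom <- function(shape = list(radiusMm = 16, foldCount = 3,
                                     foldAmplitudeMm = 2.5,
                                     thicknessMm = 3.5, elongationY = 1.9),
                        dims = c(64L, 256L, 64L),
                        spacingMm = c(1, 0.25, 1),
                        baseSubdiv = 3L, seed = 0L) {
  if (is.null(shape$elongationY)) shape$elongationY <- 1
  if (shape$thicknessMm <= 0)
    stop("makePhantom parameter error: cortical thickness must be > 0")
  if (shape$radiusMm - shape$foldAmplitudeMm - shape$thicknessMm <= 0)
    stop("makePhantom parameter error: folds self-intersect ",
         "(WM radius reaches zero)")
  dims <- as.integer(dims)
  spacingMm <- rep(spacingMm, length.out = 3)
  center <- (dims - 1) / 2 * spacingMm
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  p <- cbind((g$x - 1) * spacingMm[1], (g$y - 1) * spacingMm[2],
             (g$z - 1) * spacingMm[3])
  d <- sweep(p, 2, center)
  d[, 2] <- d[, 2] / shape$elongationY   # undo the cutting-axis stretch
  rho <- sqrt(rowSums(d^2))
  u <- d / pmax(rho, 1e-12)
  rad <- .radialShape(u, shape)
  lab <- integer(nrow(p))
  lab[rho <= rad$wm] <- 1L
  lab[rho > rad$wm & rho <= rad$pial] <- 2L
  truth <- Volume3D(array(as.numeric(lab), dims),
                    spacing = spacingMm, origin = c(0, 0, 0))
  base <- icosphereMesh(baseSubdiv, radius = 1, center = c(0, 0, 0))
  ub <- base@vertices
  radM <- .radialShape(ub, shape)
  stretch <- function(v) { v[, 2] <- v[, 2] * shape$elongationY; v }
  pial <- SurfaceMesh(sweep(stretch(ub * radM$pial), 2, center, `+`),
                      base@triangles)
  wm <- SurfaceMesh(sweep(stretch(ub * radM$wm), 2, center, `+`),
                    base@triangles)
  new("Phantom", truthVolume = truth, wmMesh = wm, pialMesh = pial,
      center = center, shape = shape, fieldSpecs = list(),
      seed = as.integer(seed))
}

#' Synthesize per-acquisition ground-truth density fields
#'
#' Each acquisition gets an analytic band-limited random field (a sum of
#' random cosine waves with wavelengths at or above `smoothnessMm`),
#' affinely mapped to the density range `range`, plus a per-acquisition
#' 8-bit intensity model (gain, offset, WM level, noise sd) emulating
#' heterogeneous acquisitions. Infinite smoothness gives a constant field.
#'
#' @param phantom a [Phantom].
#' @param acquisitions character vector of acquisition labels.
#' @param smoothnessMm minimum wavelength of the density field (mm).
#' @param range numeric(2), density range the field is scaled to.
#' @param polarityProb probability an acquisition has inverted contrast.
#' @param noiseSd intensity noise sd (gray levels) used when slicing.
#' @param seed integer seed.
#' @return the [Phantom] with `fieldSpecs` filled (one spec per
#'   acquisition).
#' @export
synthesizeTruthFields <- function(phantom, acquisitions, smoothnessMm = 16,
                                  range = c(50, 200), polarityProb = 0,
                                  noiseSd = 4, seed = phantom@seed) {
  stopifnot(length(acquisitions) >= 1)
  gmIdx <- which(phantom@truthVolume@values == 2)
  d <- dim(phantom@truthVolume@values)
  sp <- phantom@truthVolume@spacing
  ii <- arrayInd(gmIdx, d)
  gmPts <- cbind((ii[, 1] - 1) * sp[1], (ii[, 2] - 1) * sp[2],
                 (ii[, 3] - 1) * sp[3])
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_along(acquisitions), function(a) {
      K <- 12L
      if (is.finite(smoothnessMm)) {
        dirs <- matrix(stats::rnorm(3 * K), K, 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        freq <- dirs * (2 * pi / smoothnessMm) * stats::runif(K, 0.25, 1)
      } else freq <- matrix(0, K, 3)
      spec <- list(
        acquisition = acquisitions[a],
        freq = freq,
        amp = stats::rnorm(K),
        phase = stats::runif(K, 0, 2 * pi),
        lo = range[1], hi = range[2],
        gain = stats::runif(1, 0.7, 1.1),
        offset = stats::runif(1, 10, 40),
        wmLevel = stats::runif(1, 8, 25),
        flip = stats::runif(1) < polarityProb,
        noiseSd = noiseSd,
        scale = 1, shift = 0)
      raw <- .rawField(spec, gmPts)
      rng <- range(raw)
      if (diff(rng) < 1e-9) {
        spec$scale <- 0
        spec$shift <- mean(c(spec$lo, spec$hi))
      } else {
        spec$scale <- (spec$hi - spec$lo) / diff(rng)
        spec$shift <- spec$lo - rng[1] * spec$scale
      }
      spec
    })
  })
  names(specs) <- acquisitions
  phantom@fieldSpecs <- specs
  phantom
}

.rawField <- function(spec, pts) {
  acc <- numeric(nrow(pts))
  for (k in seq_len(nrow(spec$freq)))
    acc <- acc + spec$amp[k] *
      cos(pts %*% spec$freq[k, ] + spec$phase[k])[, 1]
  acc
}

#' Evaluate a phantom ground-truth density field at world points
#' @param phantom a [Phantom] with synthesized fields.
#' @param acquisition acquisition label.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return density values, clipped to the declared range.
#' @export
truthFieldValues <- function(phantom, acquisition, pts) {
  spec <- phantom@fieldSpecs[[acquisition]]
  if (is.null(spec)) stop("no truth field for acquisition ", acquisition)
  pmin(pmax(.rawField(spec, as.matrix(pts)) * spec$scale + spec$shift,
            spec$lo), spec$hi)
}

#' Ground-truth vertex field of a mesh
#' @param phantom a [Phantom] with synthesized fields.
#' @param acquisition acquisition label.
#' @param mesh a [SurfaceMesh] in reference (truth) space.
#' @return a complete [VertexField] of true densities.
#' @export
truthVertexField <- function(phantom, acquisition, mesh) {
  v <- truthFieldValues(phantom, acquisition, mesh@vertices)
  VertexField(v, rep(TRUE, length(v)))
}

#' Sampling scheme for slicing a phantom
#'
#' @param coverageFraction fraction of planes kept per acquisition cycle
#'   (emulates sparse sampling; ~0.24-0.37 in real serial datasets).
#' @param acquisitions labels cycled along the cutting axis.
#' @param dropoutProb probability a kept section is lost (mechanical loss).
#' @param nSlabs number of tissue slabs.
#' @param slabGapSections planes discarded between consecutive slabs.
#' @param fragmentAreaFraction planes whose GM area is below this fraction
#'   of the largest plane are discarded (fragment sections cut near the
#'   tissue borders are routinely lost or excluded in real datasets).
#' @param rigidJitter list(maxRotDeg, maxShiftPx): per-section rigid
#'   perturbation bounds.
#' @param slabJitter list(maxRotDeg, maxShiftPx): additional rigid offset
#'   shared by all sections of a slab (emulates per-slab deformation).
#' @param warpAmplitudePx amplitude of the per-section smooth nonlinear
#'   warp (pixels; 0 disables).
#' @return a list with class-free scheme fields, validated.
#' @export
samplingScheme <- function(coverageFraction = 0.3,
                           acquisitions = paste0("acq", 1:4),
                           dropoutProb = 0.05, nSlabs = 1L,
                           slabGapSections = 3L,
                           rigidJitter = list(maxRotDeg = 5, maxShiftPx = 3),
                           slabJitter = list(maxRotDeg = 2, maxShiftPx = 2),
                           warpAmplitudePx = 0.75,
                           fragmentAreaFraction = 0.25) {
  stopifnot(coverageFraction > 0, coverageFraction <= 1, nSlabs >= 1)
  list(coverageFraction = coverageFraction, acquisitions = acquisitions,
       dropoutProb = dropoutProb, nSlabs = as.integer(nSlabs),
       slabGapSections = as.integer(slabGapSections),
       rigidJitter = rigidJitter, slabJitter = slabJitter,
       warpAmplitudePx = warpAmplitudePx,
       fragmentAreaFraction = fragmentAreaFraction)
}

# render the un-perturbed section image of truth plane j (1-based y index)
.renderPlane <- function(phantom, j, spec) {
  v <- phantom@truthVolume
  sp <- v@spacing
  lab <- v@values[, j, ]
  d <- dim(lab)
  img <- matrix(0, d[1], d[2])
  wmSel <- lab == 1
  img[wmSel] <- spec$wmLevel
  gmSel <- which(lab == 2)
  if (length(gmSel)) {
    ii <- arrayInd(gmSel, d)
    pts <- cbind((ii[, 1] - 1) * sp[1], (j - 1) * sp[2],
                 (ii[, 2] - 1) * sp[3])
    den <- truthFieldValues(phantom, spec$acquisition, pts)
    val <- spec$offset + spec$gain * den
    if (spec$flip) val <- spec$offset + spec$gain * (spec$lo + spec$hi) - val
    img[gmSel] <- val
  }
  pmin(pmax(img, 0), 255)
}

.randomWarp <- function(dims, spacing, ampPx, coarse = 6L) {
  mk <- function() {
    f <- matrix(stats::rnorm(coarse^2), coarse, coarse)
    f <- .gaussSmooth(f, 1)
    ri <- seq(1, coarse, length.out = dims[1])
    ci <- seq(1, coarse, length.out = dims[2])
    g <- expand.grid(r = ri, c = ci)
    matrix(.bilinear2(f, g$r, g$c), dims[1], dims[2])
  }
  u1 <- mk(); u2 <- mk()
  m <- max(abs(c(u1, u2)), 1e-9)
  list(u1 * ampPx / m * spacing[1], u2 * ampPx / m * spacing[2])
}

#' Slice a phantom into a perturbed multi-acquisition section stack
#'
#' Extracts coronal planes from the truth volume, cycles acquisition labels
#' along the axis, drops planes to the requested coverage, splits the kept
#' range into slabs separated by lost planes, and perturbs every kept
#' section by a random in-plane rigid motion (plus a shared per-slab
#' offset and an optional smooth warp). Intensities follow each
#' acquisition's 8-bit model with additive Gaussian noise.
#'
#' @param phantom a [Phantom] with synthesized fields.
#' @param scheme a [samplingScheme()].
#' @param seed integer seed; fixed seed gives a bit-identical stack.
#' @return list with `stack` (a [SectionStack]; `image` refs are keys into)
#'   `images` (named list of perturbed [Image2D]s), `truth` (named list of
#'   ground-truth [TransformChain]s: the perturbation applied to each
#'   section), and `clean` (named list of unperturbed [Image2D]s).
#' @export
sliceSections <- function(phantom, scheme = samplingScheme(),
                          seed = phantom@seed) {
  v <- phantom@truthVolume
  d <- dim(v@values)
  gmPerPlane <- apply(v@values == 2, 2, sum)
  frag <- scheme$fragmentAreaFraction %||% 0
  planes <- which(gmPerPlane >= max(1, frag * max(gmPerPlane)))
  acqs <- scheme$acquisitions
  if (!length(phantom@fieldSpecs))
    stop("sliceSections: synthesize truth fields first")

  withr::with_seed(as.integer(seed), {
    # slab partition of the usable planes
    nP <- length(planes)
    slabId <- rep(seq_len(scheme$nSlabs),
                  length.out = nP,
                  each = ceiling(nP / scheme$nSlabs))[seq_len(nP)]
    # drop slab-gap planes at the downstream edge of each slab boundary
    if (scheme$nSlabs > 1 && scheme$slabGapSections > 0) {
      cut <- which(diff(slabId) != 0)
      gap <- unlist(lapply(cut, function(cc)
        (cc - scheme$slabGapSections + 1):cc))
      gap <- gap[gap >= 1]
      keepSlab <- !(seq_len(nP) %in% gap)
    } else keepSlab <- rep(TRUE, nP)

    acqLab <- rep(acqs, length.out = nP)   # labels cycle over all planes
    kept <- keepSlab & stats::runif(nP) < scheme$coverageFraction
    kept <- kept & stats::runif(nP) >= scheme$dropoutProb
    if (!any(kept))
      stop("sliceSections: no sections kept (coverage/dropout too severe)")

    slabRigids <- lapply(seq_len(scheme$nSlabs), function(s)
      list(rot = stats::runif(1, -1, 1) * scheme$slabJitter$maxRotDeg,
           shift = stats::runif(2, -1, 1) * scheme$slabJitter$maxShiftPx))

    recs <- list(); images <- list(); truth <- list(); clean <- list()
    inPlaneCenter <- phantom@center[c(1, 3)]
    for (k in which(kept)) {
      j <- planes[k]
      acq <- acqLab[k]
      spec <- phantom@fieldSpecs[[acq]]
      base <- .renderPlane(phantom, j, spec)
      sp2 <- v@spacing[c(1, 3)]
      img0 <- Image2D(base, spacing = sp2, origin = c(0, 0))
      rot <- stats::runif(1, -1, 1) * scheme$rigidJitter$maxRotDeg +
        slabRigids[[slabId[k]]]$rot
      shift <- stats::runif(2, -1, 1) * scheme$rigidJitter$maxShiftPx *
        sp2 + slabRigids[[slabId[k]]]$shift * sp2
      pert <- Rigid2D(thetaDeg = rot, translation = shift,
                      center = inPlaneCenter)
      warps <- list()
      if (scheme$warpAmplitudePx > 0) {
        u <- .randomWarp(dim(base), sp2, scheme$warpAmplitudePx)
        warps <- list(Deformation2D(u, spacing = sp2, origin = c(0, 0)))
      }
      chain <- TransformChain(rigid = pert, warps = warps)
      out <- applyTransform2D(img0, chain, outGrid = img0, mode = "linear")
      noisy <- out@values +
        stats::rnorm(length(out@values), 0, spec$noiseSd) *
        (out@values > 0)
      vals <- round(pmin(pmax(noisy, 0), 255))
      key <- sprintf("s%d_p%03d_%s", slabId[k], j - 1L, acq)
      images[[key]] <- Image2D(vals, spacing = sp2, origin = c(0, 0))
      clean[[key]] <- img0
      truth[[key]] <- chain
      recs[[length(recs) + 1L]] <- data.frame(
        slab = slabId[k], sample = j - 1L, acquisition = acq,
        image = key, pixel_size_um = sp2[1] * 1000,
        section_thickness_um = v@spacing[2] * 1000,
        qc_pass = TRUE, exclude_reason = NA_character_)
    }
    df <- do.call(rbind, recs)
    stack <- SectionStack(df, axis = "coronal", speciesTag = "phantom")
    nPerAcq <- table(df$acquisition)
    lowCoverage <- any(nPerAcq < 2) || length(nPerAcq) < length(acqs)
    if (lowCoverage)
      warning("sliceSections: an acquisition has fewer than 2 sections")
    list(stack = stack, images = images, truth = truth, clean = clean,
         lowCoverage = lowCoverage)
  })
}

#' Write a phantom dataset to disk in the real-data layout
#'
#' Produces a CSV manifest, 8-bit PNG sections, the NIfTI truth volume and
#' GM mask, and OBJ surface meshes, so the reconstruction consumes phantom
#' and real datasets identically.
#'
#' @param phantom a [Phantom] with fields.
#' @param sliced output of [sliceSections()].
#' @param dir output directory (created).
#' @return the manifest path, invisibly.
#' @export
writePhantomDataset <- function(phantom, sliced, dir) {
  dir.create(file.path(dir, "sections"), recursive = TRUE,
             showWarnings = FALSE)
  rec <- sliced$stack@records
  for (i in seq_len(nrow(rec))) {
    key <- rec$image[i]
    path <- file.path(dir, "sections", paste0(key, ".png"))
    writeSectionImage(sliced$images[[key]], path)
    rec$image[i] <- file.path("sections", paste0(key, ".png"))
  }
  stack <- SectionStack(rec, axis = sliced$stack@axis,
                        speciesTag = sliced$stack@speciesTag)
  writeManifest(stack, file.path(dir, "manifest.csv"))
  writeVolumeNifti(phantom@truthVolume, file.path(dir, "truth_labels.nii.gz"))
  gm <- GMMask3D(1 * (phantom@truthVolume@values == 2),
                 spacing = phantom@truthVolume@spacing,
                 origin = phantom@truthVolume@origin)
  writeVolumeNifti(gm, file.path(dir, "reference_gm.nii.gz"))
  writeMeshObj(phantom@wmMesh, file.path(dir, "wm_surface.obj"))
  writeMeshObj(phantom@pialMesh, file.path(dir, "pial_surface.obj"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Binary GM mask of the phantom truth volume
#' @param phantom a [Phantom].
#' @return a binary [GMMask3D] on the truth grid.
#' @export
phantomGMMask <- function(phantom) {
  GMMask3D(1 * (phantom@truthVolume@values == 2),
           spacing = phantom@truthVolume@spacing,
           origin = phantom@truthVolume@origin)
}
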