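# Shared fixtures, memoised so expensive phantoms and pipeline runs are
# built once per test session.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small phantom for unit tests (coarse grid, quick to build)
smallPhantom <- function() fixture("smallPhantom", {
  synthesizeTruthFields(
    makePhantom(shape = list(radiusMm = 10, foldCount = 3,
                             foldAmplitudeMm = 1.5, thicknessMm = 3,
                             elongationY = 1.5),
                dims = c(40L, 96L, 40L), spacingMm = c(1, 0.4, 1),
                baseSubdiv = 2L, seed = 7L),
    acquisitions = c("ampa", "gaba"), seed = 7)
})

smallSlices <- function() fixture("smallSlices", {
  suppressWarnings(sliceSections(
    smallPhantom(),
    samplingScheme(coverageFraction = 0.5,
                   acquisitions = c("ampa", "gaba")),
    seed = 11))
})

# default-condition phantom (the study conditions): 4 acquisitions,
# 64^3 reference at 1 mm
defaultPhantom <- function(seed = 0L) fixture(paste0("defaultPhantom", seed), {
  synthesizeTruthFields(makePhantom(seed = as.integer(seed)),
                        paste0("acq", 1:4), seed = seed)
})

truthMask2D <- function(phantom, sample) {
  pl <- extractPlane(phantom@truthVolume, sample + 1L)
  GMMask2D(1 * (pl@values == 2), spacing = pl@spacing, origin = pl@origin)
}

referenceGM <- function(phantom, resMm = 1) {
  v <- resampleVolume(phantomGMMask(phantom), resMm, mode = "linear")
  GMMask3D(1 * (v@values > 0.5), spacing = v@spacing, origin = v@origin)
}

slabBoundsFromStack <- function(stack) {
  rec <- stack@records[stack@records$qc_pass, ]
  thick <- rec$section_thickness_um[1] / 1000
  do.call(rbind, lapply(sort(unique(rec$slab)), function(s) {
    ys <- rec$sample[rec$slab == s] * thick
    data.frame(slab = s, anteriorMm = max(ys) + thick,
               posteriorMm = min(ys) - thick)
  }))
}

# random binary blob masks for Dice-oracle tests
randomMask <- function(n = 20, p = 0.35) {
  m <- matrix(stats::rbinom(n * n, 1, p), n, n)
  GMMask2D(m, spacing = c(1, 1))
}

# brute-force oracles -----------------------------------------------------

diceOracle <- function(a, b) {
  A <- which(as.array(a) > 0.5)
  B <- which(as.array(b) > 0.5)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

windowedDiceOracle <- function(p, r, w = 5L) {
  p <- 1 * (as.matrix(p) > 0.5); r <- 1 * (as.matrix(r) > 0.5)
  vals <- c()
  for (i in seq_len(nrow(p) - w + 1)) for (j in seq_len(ncol(p) - w + 1)) {
    pw <- p[i:(i + w - 1), j:(j + w - 1)]
    rw <- r[i:(i + w - 1), j:(j + w - 1)]
    if (sum(pw) == 0) next
    vals <- c(vals, 2 * sum(pw * rw) / (sum(pw) + sum(rw)))
  }
  mean(vals)
}

otsuOracle <- function(values) {
  v <- as.numeric(values)
  lo <- if (min(v) >= 0 && max(v) <= 255) 0 else min(v)
  hi <- if (min(v) >= 0 && max(v) <= 255) 255 else max(v)
  breaks <- seq(lo, hi, length.out = 257)
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
              256L)
  centers <- (breaks[-1] + breaks[-257]) / 2
  best <- -Inf; bestT <- NA
  for (t in 1:255) {
    g0 <- v[bin <= t]; g1 <- v[bin > t]
    if (!length(g0) || !length(g1)) next
    # between-class variance with bin-centre means (as the 256-bin method)
    m0 <- mean(centers[bin[bin <= t]]); m1 <- mean(centers[bin[bin > t]])
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-12) { best <- sb; bestT <- t }
  }
  bestT - 1L   # 0-based bin index
}

# ---- study-condition fixtures (shared across the acceptance checks) ----

# the full reconstruction under the study conditions: 64^3 1 mm reference,
# 4 acquisitions, 30% coverage, 2 slabs, default jitter, schedule 4-2-1 mm
studyConfig <- function(seed = 0L) {
  ph <- defaultPhantom(seed)
  sl <- suppressWarnings(sliceSections(
    ph, samplingScheme(coverageFraction = 0.3, nSlabs = 2), seed = seed))
  list(phantom = ph, sliced = sl,
       config = pipelineConfig(
         manifest = sl$stack, referenceGM = referenceGM(ph, 1),
         wmSurface = ph@wmMesh, pialSurface = ph@pialMesh,
         images = sl$images, schedule = c(4, 2, 1), nDepthSurfaces = 8L,
         boundsPerSlab = slabBoundsFromStack(sl$stack), seed = seed))
}

studyRun <- function() fixture("studyRun", {
  sc <- studyConfig(0L)
  list(setup = sc, out = runReconstruction(sc$config))
})

studyMetrics <- function() fixture("studyMetrics",
  alignmentMetrics(studyRun()$out))

# a compact full-pipeline configuration for the determinism check (the
# pipeline code path is identical to the study configuration; determinism
# is a property of the code, not of the problem size)
determinismConfig <- function(seed = 0L) {
  ph <- synthesizeTruthFields(
    makePhantom(shape = list(radiusMm = 10, foldCount = 3,
                             foldAmplitudeMm = 1.5, thicknessMm = 3,
                             elongationY = 1.2),
                dims = c(48L, 96L, 48L), spacingMm = c(1, 0.5, 1),
                baseSubdiv = 2L, seed = seed),
    c("acqA", "acqB"), seed = seed)
  sl <- suppressWarnings(sliceSections(
    ph, samplingScheme(coverageFraction = 0.4,
                       acquisitions = c("acqA", "acqB"), nSlabs = 2),
    seed = seed))
  pipelineConfig(manifest = sl$stack, referenceGM = referenceGM(ph, 1),
                 wmSurface = ph@wmMesh, pialSurface = ph@pialMesh,
                 images = sl$images, schedule = c(4, 2),
                 nDepthSurfaces = 6L,
                 boundsPerSlab = slabBoundsFromStack(sl$stack),
                 seed = seed)
}

# identity-transform stage-3 harness: unperturbed sections sampled onto
# 20 depth surfaces, spherical interpolation, projection (shared by the
# interpolation and patch checks)
identityStage3 <- function() fixture("identityStage3", {
  ph <- defaultPhantom(0L)
  sch <- samplingScheme(coverageFraction = 0.3,
                        acquisitions = paste0("acq", 1:4), nSlabs = 1,
                        rigidJitter = list(maxRotDeg = 0, maxShiftPx = 0),
                        slabJitter = list(maxRotDeg = 0, maxShiftPx = 0),
                        warpAmplitudePx = 0, dropoutProb = 0)
  sl <- suppressWarnings(sliceSections(ph, sch, seed = 0))
  rec <- records(sl$stack)
  chains <- stats::setNames(rep(list(TransformChain()), nrow(rec)),
                            rec$image)
  gmm <- lapply(stats::setNames(rec$image, rec$image), function(k)
    segmenterPredict(otsuSegmenter(), sl$images[[k]]))
  ds0 <- generateDepthSurfaces(ph@wmMesh, ph@pialMesh, 18)
  n <- upsampleOrder(ph@pialMesh, 2 * 1)
  ds <- DepthSurfaceSet(lapply(ds0@meshes, upsampleMesh, n = n),
                        ds0@depths)
  mid <- ds@meshes[[10]]
  sphere <- inflateToSphere(mid, center = ph@center)
  refGMf <- resampleVolume(phantomGMMask(ph), 1, mode = "linear")
  ribbon <- GMMask3D(1 * (refGMf@values > 0.5), spacing = refGMf@spacing,
                     origin = refGMf@origin)
  fs <- sampleSectionsToVertices(sl$stack, chains, ds, sl$images, "acq1",
                                 gmMasks = gmm)
  list(phantom = ph, sliced = sl, depthSet = ds, sphere = sphere,
       fields = fs, ribbon = ribbon, chains = chains, gmMasks = gmm)
})
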