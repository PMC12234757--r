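test_that("phantom construction is deterministic and matches the analytic
           shell volume when folds are off", {
  p1 <- makePhantom(dims = c(32, 64, 32), spacingMm = c(1, 0.5, 1),
                    shape = list(radiusMm = 10, foldCount = 3,
                                 foldAmplitudeMm = 1, thicknessMm = 3,
                                 elongationY = 1.2),
                    baseSubdiv = 2, seed = 3)
  p2 <- makePhantom(dims = c(32, 64, 32), spacingMm = c(1, 0.5, 1),
                    shape = list(radiusMm = 10, foldCount = 3,
                                 foldAmplitudeMm = 1, thicknessMm = 3,
                                 elongationY = 1.2),
                    baseSubdiv = 2, seed = 3)
  expect_identical(p1@truthVolume@values, p2@truthVolume@values)
  expect_identical(p1@pialMesh@vertices, p2@pialMesh@vertices)

  # zero fold amplitude, no elongation: spherical shell with analytic
  # volume 4/3 pi (R^3 - (R - t)^3)
  ps <- makePhantom(dims = c(48, 96, 48), spacingMm = c(1, 0.5, 1),
                    shape = list(radiusMm = 12, foldCount = 3,
                                 foldAmplitudeMm = 0, thicknessMm = 3,
                                 elongationY = 1),
                    baseSubdiv = 2, seed = 0)
  gmVol <- sum(ps@truthVolume@values == 2) * prod(ps@truthVolume@spacing)
  analytic <- 4 / 3 * pi * (12^3 - 9^3)
  expect_lt(abs(gmVol - analytic) / analytic, 0.05)

  expect_error(makePhantom(shape = list(radiusMm = 10, foldCount = 3,
                                        foldAmplitudeMm = 1,
                                        thicknessMm = 0, elongationY = 1)),
               "thickness")
  expect_error(makePhantom(shape = list(radiusMm = 4, foldCount = 3,
                                        foldAmplitudeMm = 1,
                                        thicknessMm = 3.5, elongationY = 1)),
               "self-intersect")
})

test_that("GM voxels lie inside the WM-pial ribbon (point-in-ribbon)", {
  ph <- smallPhantom()
  v <- ph@truthVolume
  idx <- which(v@values == 2, arr.ind = TRUE)
  pts <- sweep((idx - 1) %*% diag(v@spacing), 2, v@origin, `+`)
  d <- sweep(pts, 2, ph@center)
  d[, 2] <- d[, 2] / ph@shape$elongationY
  rho <- sqrt(rowSums(d^2))
  u <- d / rho
  rad <- recortex:::.radialShape(u, ph@shape)
  # half-voxel tolerance at the borders
  inRibbon <- rho >= rad$wm - 0.75 & rho <= rad$pial + 0.75
  expect_gte(mean(inRibbon), 0.99)
})

test_that("truth fields are deterministic, ranged, and constant in the
           infinite-smoothness limit", {
  ph <- smallPhantom()
  base <- makePhantom(dims = c(32, 64, 32), spacingMm = c(1, 0.5, 1),
                      shape = list(radiusMm = 10, foldCount = 3,
                                   foldAmplitudeMm = 1, thicknessMm = 3,
                                   elongationY = 1.2),
                      baseSubdiv = 2, seed = 1)
  a <- synthesizeTruthFields(base, c("x", "y"), seed = 5)
  b <- synthesizeTruthFields(base, c("x", "y"), seed = 5)
  expect_identical(a@fieldSpecs$x$amp, b@fieldSpecs$x$amp)

  for (sd in 1:10) {
    f <- synthesizeTruthFields(base, "x", range = c(50, 200), seed = sd)
    vals <- truthFieldValues(f, "x", f@pialMesh@vertices)
    expect_gte(min(vals), 50)
    expect_lte(max(vals), 200)
  }

  const <- synthesizeTruthFields(base, "x", smoothnessMm = Inf, seed = 2)
  vals <- truthFieldValues(const, "x", const@pialMesh@vertices)
  expect_equal(max(vals) - min(vals), 0)
})

test_that("slicing cycles acquisitions, honours coverage binomially, and
           is seed-deterministic", {
  ph <- smallPhantom()
  sch <- samplingScheme(coverageFraction = 0.3,
                        acquisitions = c("ampa", "gaba"), dropoutProb = 0)
  s1 <- suppressWarnings(sliceSections(ph, sch, seed = 9))
  s2 <- suppressWarnings(sliceSections(ph, sch, seed = 9))
  expect_identical(s1$stack@records, s2$stack@records)
  expect_identical(s1$images[[1]]@values, s2$images[[1]]@values)

  # kept count within a generous binomial band around coverage * planes
  gmPerPlane <- apply(ph@truthVolume@values == 2, 2, sum)
  nPlanes <- sum(gmPerPlane >= 0.25 * max(gmPerPlane))
  n <- nrow(s1$stack@records)
  expect_gt(n, 0.3 * nPlanes - 3 * sqrt(nPlanes * 0.3 * 0.7))
  expect_lt(n, 0.3 * nPlanes + 3 * sqrt(nPlanes * 0.3 * 0.7))

  # dropping everything is an error
  expect_error(suppressWarnings(sliceSections(
    ph, samplingScheme(coverageFraction = 1e-6,
                       acquisitions = "ampa"), seed = 1)),
    "no sections kept")
})

test_that("inverting the ground-truth perturbation recovers the clean
           section to within one gray level", {
  sl <- smallSlices()
  keys <- utils::head(names(sl$images), 4)
  for (key in keys) {
    chain <- sl$truth[[key]]
    pert <- sl$images[[key]]
    # invert: undo warps (numeric inverse), then the rigid
    img <- pert
    for (w in rev(chain@warps))
      img <- applyTransform2D(img, invertDeformation(w), outGrid = img)
    img <- applyTransform2D(img, invertRigid2D(chain@rigid), outGrid = img)
    clean <- sl$clean[[key]]
    # interior band: exclude a border where background fill enters
    d <- dim(clean@values)
    band <- list(8:(d[1] - 8), 8:(d[2] - 8))
    err <- abs(img@values[band[[1]], band[[2]]] -
               clean@values[band[[1]], band[[2]]])
    # mean abs error dominated by the additive intensity noise (sd 4)
    expect_lt(mean(err), 2 + 2 * 4)
  }
})

test_that("a phantom dataset written to disk reloads as a valid input", {
  tmp <- withr::local_tempdir()
  ph <- smallPhantom()
  sl <- smallSlices()
  writePhantomDataset(ph, sl, tmp)
  stack <- loadManifest(file.path(tmp, "manifest.csv"))
  expect_equal(nrow(records(stack)), nrow(records(sl$stack)))
  rec <- records(stack)
  img <- readSectionImage(file.path(tmp, rec$image[1]),
                          rec$pixel_size_um[1])
  key <- records(sl$stack)$image[1]
  expect_equal(img@values, sl$images[[key]]@values, tolerance = 0.51)
  gm <- readVolumeNifti(file.path(tmp, "reference_gm.nii.gz"))
  expect_equal(dim(gm@values), dim(ph@truthVolume@values))
  mesh <- readMeshObj(file.path(tmp, "pial_surface.obj"))
  expect_equal(mesh@vertices, ph@pialMesh@vertices, tolerance = 1e-6)
  expect_identical(mesh@triangles, ph@pialMesh@triangles)
})
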