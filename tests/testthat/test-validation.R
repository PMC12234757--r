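test_that("windowed Dice skips empty prediction windows and matches the
           sliding-window oracle", {
  m <- randomMask(30)
  expect_equal(windowedDice(m, m), 1)

  # damaged prediction: a whole piece of tissue lost, the remainder
  # perfectly aligned. Windows over the lost piece contain no predicted
  # tissue and are skipped, so the windowed score stays exactly 1 while
  # plain Dice is penalised. (The lost piece is separated from the rest by
  # more than a window width; damage cutting straight through tissue still
  # costs the few windows that straddle the cut.)
  two <- matrix(0, 30, 30)
  two[5:12, 5:12] <- 1     # kept blob
  two[5:12, 22:29] <- 1    # blob that will be lost
  full <- GMMask2D(two)
  damaged <- GMMask2D(two * (col(two) < 20))
  expect_equal(windowedDice(damaged, full), 1)
  expect_lt(dice(damaged, full), 1)
  # cutting through tissue penalises only boundary windows
  ph <- smallPhantom()
  ring <- truthMask2D(ph, 40)
  half <- ring
  half@values[, seq_len(ncol(ring@values) / 2)] <- 0
  expect_gt(windowedDice(half, ring), dice(half, ring))

  withr::with_seed(19, {
    for (i in 1:50) {
      p <- randomMask(30); r <- randomMask(30)
      expect_equal(windowedDice(p, r), windowedDiceOracle(p@values, r@values),
                   tolerance = 1e-12)
    }
  })
  expect_error(windowedDice(GMMask2D(matrix(0, 30, 30)), m), "no tissue")
})

test_that("inter-section Dice averages anterior/posterior neighbours with
           single-sided ends", {
  ms <- lapply(1:4, function(i) randomMask(15))
  same <- intersectionDice(rep(ms[1], 4))
  expect_equal(same, rep(1, 4))

  d <- intersectionDice(ms)
  oracle <- c(dice(ms[[1]], ms[[2]]),
              mean(c(dice(ms[[2]], ms[[1]]), dice(ms[[2]], ms[[3]]))),
              mean(c(dice(ms[[3]], ms[[2]]), dice(ms[[3]], ms[[4]]))),
              dice(ms[[4]], ms[[3]]))
  expect_equal(d, oracle)
  expect_error(intersectionDice(ms[1]), "at least 2")

  # unsorted sample positions are honoured
  d2 <- intersectionDice(ms[c(3, 1, 2, 4)], samples = c(3, 1, 2, 4))
  expect_equal(d2, oracle[c(3, 1, 2, 4)])
})

test_that("patch validation is deterministic, exact on constant fields and
           accurate on smooth fields", {
  ph <- smallPhantom()
  sl <- smallSlices()
  ds0 <- generateDepthSurfaces(ph@wmMesh, ph@pialMesh, 8)
  n <- upsampleOrder(ph@pialMesh, 2)
  mid <- upsampleMesh(ds0@meshes[[5]], n = n)
  sphere <- inflateToSphere(mid, center = ph@center)
  idChains <- stats::setNames(rep(list(TransformChain()),
                                  nrow(records(sl$stack))),
                              records(sl$stack)$image)
  fs <- sampleSectionsToVertices(sl$stack, idChains,
                                 DepthSurfaceSet(list(mid, mid), c(0, 1)),
                                 sl$clean, "ampa")
  known <- fs[[1]]@known

  # constant field: every seed reproduces the core mean exactly
  fc <- VertexField(ifelse(known, 5, NA_real_), known)
  spec <- patchSpec(nSeeds = 40, distanceWindowMm = c(0.01, 50), seed = 1)
  outc <- patchInterpolationValidation(sphere, fc, spec,
                                       distanceMesh = mid)
  expect_true(outc$exactMatch)
  expect_equal(outc$estMeans, outc$trueMeans, tolerance = 1e-9)

  # smooth truth field: high correlation between true and estimated means
  fv <- VertexField(ifelse(known,
                           truthFieldValues(ph, "ampa", mid@vertices), NA),
                    known)
  spec2 <- patchSpec(nSeeds = 150, distanceWindowMm = c(0.01, 50), seed = 2)
  out1 <- patchInterpolationValidation(sphere, fv, spec2,
                                       distanceMesh = mid)
  out2 <- patchInterpolationValidation(sphere, fv, spec2,
                                       distanceMesh = mid)
  expect_identical(out1$trueMeans, out2$trueMeans)   # fixed seed
  expect_identical(out1$estMeans, out2$estMeans)
  expect_gte(out1$r2, 0.9)
})

test_that("ROI parcellation hits the target region count and partitions
           the tissue", {
  # uniform strip of area 10 A with target A: about 10 regions
  strip <- Image2D(matrix(100, 20, 50), spacing = c(1, 1))
  mask <- GMMask2D(matrix(1, 20, 50))
  parc <- makeRoiParcellation(strip, mask, targetMeanAreaMm2 = 100)
  k <- length(setdiff(unique(as.integer(parc@values)), 0))
  expect_gte(k, 8); expect_lte(k, 12)
  # exact partition of the tissue; background stays 0
  expect_true(all(parc@values[mask@values > 0.5] > 0))
  expect_true(all(parc@values[mask@values <= 0.5] == 0))

  single <- makeRoiParcellation(Image2D(matrix(5, 3, 3)),
                                GMMask2D(diag(3) * 0 + {
                                  m <- matrix(0, 3, 3); m[2, 2] <- 1; m
                                }), 21)
  expect_equal(sort(unique(as.integer(single@values))), c(0L, 1L))
  expect_error(makeRoiParcellation(strip, GMMask2D(matrix(0, 20, 50)), 21),
               "empty")
})

test_that("ROI accuracy is exactly 1 under identity transforms and
           degrades gracefully under warps", {
  ph <- smallPhantom()
  sl <- smallSlices()
  rec <- records(sl$stack)
  key <- rec$image[4]
  img <- sl$clean[[key]]
  mask <- truthMask2D(ph, rec$sample[4])
  parc <- makeRoiParcellation(img, mask, targetMeanAreaMm2 = 40)
  outGrid <- list(dim = dim(img@values), spacing = img@spacing,
                  origin = img@origin)

  accId <- roiAccuracy(img, parc, TransformChain(), outGrid)
  expect_equal(accId$acc2d, rep(1, nrow(accId)))

  # constant section: linear resampling of a constant is exact
  const <- Image2D(matrix(0, nrow(img@values), ncol(img@values)) +
                   77 * (mask@values > 0.5), img@spacing, img@origin)
  tsmall <- TransformChain(rigid = Rigid2D(thetaDeg = 3,
                                           translation = c(1, 0.5),
                                           center = ph@center[c(1, 3)]))
  accC <- roiAccuracy(const, parc, tsmall, outGrid)
  # every ROI of the thin ribbon touches the tissue border, where
  # resampling mixes in background; the interior of a constant section is
  # still reproduced exactly, so the aggregate stays high
  expect_gte(mean(accC$acc2d), 0.9)
  warped <- applyTransform2D(const, tsmall, outGrid = const)
  interior <- warped@values[abs(warped@values - 77) < 1e-9]
  expect_gt(length(interior), 50)   # an exact constant core survives

  accW <- roiAccuracy(img, parc, tsmall, outGrid)
  expect_gte(mean(accW$acc2d), 0.9)
})

test_that("regional regression returns OLS estimates matching the
           normal-equations oracle", {
  a <- c(1, 2, 3, 4, 5)
  r1 <- regionalRegression(a, a)
  expect_equal(r1$slope, 1); expect_equal(r1$r2, 1)
  r2 <- regionalRegression(a, 2 * a + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$r2, 1)

  withr::with_seed(20, {
    x <- rnorm(30); y <- 1.4 * x + rnorm(30, 0, 0.3)
    fit <- regionalRegression(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  })
  expect_error(regionalRegression(rep(1, 5), a), "variance")
  expect_error(regionalRegression(1:2, 1:2), "3")
})

test_that("SUVR divides by the WM mean and is ratio-invariant", {
  v <- Volume3D(array(runif(4^3, 1, 5), c(4, 4, 4)))
  wm <- GMMask3D(array(c(rep(1, 16), rep(0, 48)), c(4, 4, 4)))
  s1 <- suvr(v, wm)
  wmMean <- mean(v@values[wm@values > 0.5])
  expect_equal(s1@values, v@values / wmMean)
  # volume equal to its WM mean everywhere -> all ones
  flat <- Volume3D(array(7, c(4, 4, 4)))
  expect_equal(suvr(flat, wm)@values, array(1, c(4, 4, 4)))
  # doubling the input changes nothing
  s2 <- suvr(Volume3D(2 * v@values), wm)
  expect_equal(s2@values, s1@values)
  expect_error(suvr(Volume3D(array(0, c(4, 4, 4))), wm), "zero")
})

test_that("the permutation test matches exhaustive enumeration and
           separates obvious groups", {
  # identical lists: observed statistic 0, p near 1
  same <- permutationCorrTest(rep(0.5, 5), rep(0.5, 5), nPerm = 500,
                              seed = 1)
  expect_gte(same$p, 0.99)

  w <- rep(0.9, 5); b <- rep(0.1, 5)
  res <- permutationCorrTest(w, b, nPerm = 10000, seed = 2)
  expect_lte(res$p, 0.01)

  # exhaustive oracle over all choose(10, 5) label splits
  pooled <- c(w, b)
  splits <- utils::combn(10, 5)
  stats <- apply(splits, 2, function(ix)
    abs(mean(pooled[ix]) - mean(pooled[-ix])))
  exact <- mean(stats >= res$observed - 1e-12)
  expect_lt(abs(res$p - exact), 0.01)

  expect_warning(permutationCorrTest(w, b, nPerm = 50, seed = 1), "nPerm")
})

test_that("permutation p-values are monotone in effect size", {
  withr::with_seed(23, {
    base <- rnorm(8, 0.5, 0.1)
    ps <- vapply(c(0, 0.15, 0.4), function(shift)
      permutationCorrTest(base + shift, rnorm(8, 0.5, 0.1),
                          nPerm = 400, seed = 3)$p, numeric(1))
  })
  expect_true(all(diff(ps) <= 0))
})
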