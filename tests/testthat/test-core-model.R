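test_that("manifest loading enforces schema, uniqueness and ordering", {
  tmp <- withr::local_tempdir()
  df <- data.frame(slab = c(2, 1, 1), sample = c(4, 9, 2),
                   acquisition = c("gaba", "ampa", "cellbody"),
                   image = c("a.png", "b.png", "c.png"),
                   pixel_size_um = 50)
  path <- file.path(tmp, "manifest.csv")
  write.csv(df, path, row.names = FALSE)
  stack <- loadManifest(path)
  rec <- records(stack)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$slab, c(1L, 1L, 2L))        # sorted by (slab, sample)
  expect_equal(rec$sample, c(2L, 9L, 4L))
  expect_true(all(rec$qc_pass))

  # round trip preserves semantic content
  out <- file.path(tmp, "roundtrip.csv")
  writeManifest(stack, out)
  rec2 <- records(loadManifest(out))
  expect_equal(rec2[names(rec)], rec)

  # schema error names the missing column
  write.csv(df[, setdiff(names(df), "acquisition")],
            file.path(tmp, "bad.csv"), row.names = FALSE)
  expect_error(loadManifest(file.path(tmp, "bad.csv")), "acquisition")

  # duplicate (slab, sample) is an integrity error
  dup <- rbind(df, data.frame(slab = 1, sample = 9, acquisition = "x",
                              image = "d.png", pixel_size_um = 50))
  write.csv(dup, file.path(tmp, "dup.csv"), row.names = FALSE)
  expect_error(loadManifest(file.path(tmp, "dup.csv")), "duplicate")
})

test_that("dice matches its definition, the empty-empty convention, and a
           set-arithmetic oracle", {
  a <- GMMask2D(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2))
  b <- GMMask2D(matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)   # |A|=4, |B|=4, overlap 2
  disj <- GMMask2D(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2))
  expect_equal(dice(a, disj), 0)
  empty <- GMMask2D(matrix(0, 2, 4))
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, GMMask2D(matrix(0, 3, 3))), "mismatch")

  withr::with_seed(42, {
    for (i in 1:100) {
      m1 <- randomMask(); m2 <- randomMask()
      expect_identical(dice(m1, m2), diceOracle(m1@values, m2@values))
      expect_identical(dice(m1, m2), dice(m2, m1))
    }
  })
})

test_that("2D transform application: identity, integer shifts, binarity", {
  withr::with_seed(1, img <- Image2D(matrix(runif(400), 20, 20)))
  id <- Rigid2D()
  expect_equal(applyTransform2D(img, id, img)@values, img@values)

  # pure integer translation with nearest interpolation equals index
  # shifting on the interior
  t <- Rigid2D(translation = c(3, -2))
  out <- applyTransform2D(img, t, img, mode = "nearest")
  # pull-back: out(r, c) = img(r - 3, c + 2)
  expect_equal(out@values[5:18, 3:15], img@values[2:15, 5:17])

  # binary masks stay binary under nearest resampling through a chain
  m <- randomMask(20)
  ch <- TransformChain(rigid = Rigid2D(thetaDeg = 17, translation = c(1.3, -0.7),
                                       center = c(10, 10)))
  mw <- applyTransform2D(m, ch, m, mode = "nearest")
  expect_true(all(mw@values %in% c(0, 1)))
})

test_that("transform composition agrees with sequential application", {
  # bilinear resampling reproduces affine images exactly, so applying two
  # rigids in sequence must agree with the composed transform to floating
  # tolerance on such images
  base <- outer(seq_len(40), seq_len(40), function(r, c) 0.3 * r - 0.1 * c)
  img <- Image2D(base)
  t1 <- Rigid2D(thetaDeg = 5, translation = c(1, 2), center = c(20, 20))
  t2 <- Rigid2D(thetaDeg = -3, translation = c(-2, 0.5), center = c(20, 20))
  seq2 <- applyTransform2D(applyTransform2D(img, t1, img), t2, img)
  comp <- applyTransform2D(img, composeRigid2D(t2, t1), img)
  # interior comparison: edges see the background fill
  expect_lt(max(abs(seq2@values[12:28, 12:28] - comp@values[12:28, 12:28])),
            1e-6)
  # exact composition property on points
  pts <- matrix(runif(20, 5, 35), 10, 2)
  expect_equal(rigidForward(t2, rigidForward(t1, pts)),
               rigidForward(composeRigid2D(t2, t1), pts), tolerance = 1e-10)
  # inverse property
  inv <- invertRigid2D(t1)
  expect_equal(rigidForward(inv, rigidForward(t1, pts)), pts,
               tolerance = 1e-10)
})

test_that("volume resampling preserves constants and matches the
           block-mean oracle for an exact factor-2 downsample", {
  const <- Volume3D(array(3.7, c(8, 8, 8)))
  expect_equal(resampleVolume(const, 2)@values, array(3.7, c(4, 4, 4)))

  withr::with_seed(3, v <- Volume3D(array(runif(8^3), c(8, 8, 8))))
  down <- resampleVolume(v, 2)
  oracle <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    oracle[i, j, k] <- mean(v@values[(2 * i - 1):(2 * i),
                                     (2 * j - 1):(2 * j),
                                     (2 * k - 1):(2 * k)])
  expect_equal(down@values, oracle, tolerance = 1e-12)

  same <- resampleVolume(v, 1)
  expect_equal(same@values, v@values, tolerance = 1e-12)
})

test_that("displacement fields invert numerically and transforms persist
           to disk", {
  withr::with_seed(4, {
    u1 <- .5 * matrix(sin(seq(0, 2, length.out = 900)), 30, 30)
    u2 <- .5 * matrix(cos(seq(0, 2, length.out = 900)), 30, 30)
  })
  f <- Deformation2D(list(u1, u2))
  finv <- invertDeformation(f)
  # compose: x + u(x) followed by inverse should return to x
  g <- expand.grid(r = 5:25, c = 5:25)
  pts <- cbind(g$r - 1, g$c - 1)
  fwd <- pts + recortex:::.fieldAt2(f, pts)
  back <- fwd + recortex:::.fieldAt2(finv, fwd)
  expect_lt(median(sqrt(rowSums((back - pts)^2))), 0.5)

  tmp <- withr::local_tempdir()
  chain <- TransformChain(rigid = Rigid2D(thetaDeg = 3, translation = c(1, 2),
                                          center = c(5, 5)),
                          warps = list(f))
  writeTransformChain(chain, file.path(tmp, "sec1"))
  back2 <- readTransformChain(file.path(tmp, "sec1"))
  expect_equal(back2@rigid@thetaDeg, 3)
  expect_equal(back2@rigid@translation, c(1, 2))
  expect_equal(back2@warps[[1]]@u[[1]], u1, tolerance = 1e-6)
})

test_that("section image and volume round trips through PNG and NIfTI", {
  tmp <- withr::local_tempdir()
  withr::with_seed(5, img <- Image2D(matrix(sample(0:255, 100, TRUE), 10),
                                     spacing = c(0.05, 0.05)))
  p <- file.path(tmp, "sec.png")
  writeSectionImage(img, p)
  back <- readSectionImage(p, pixelSizeUm = 50)
  expect_equal(back@values, img@values, tolerance = 0.51)

  v <- Volume3D(array(rnorm(4^3), c(4, 4, 4)), spacing = c(1, 2, 1),
                origin = c(3, 4, 5))
  np <- file.path(tmp, "vol.nii.gz")
  writeVolumeNifti(v, np)
  vb <- readVolumeNifti(np)
  expect_equal(vb@values, v@values, tolerance = 1e-6)
  expect_equal(vb@spacing, v@spacing, tolerance = 1e-6)
})
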