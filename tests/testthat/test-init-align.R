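test_that("Michelson contrast follows its definition", {
  full <- GMMask2D(matrix(1, 4, 4))
  expect_equal(michelsonContrast(Image2D(matrix(100, 4, 4)), full), 0)
  expect_equal(michelsonContrast(
    Image2D(matrix(c(0, 255, 100, 100), 2, 2)), GMMask2D(matrix(1, 2, 2))),
    1)
  expect_equal(michelsonContrast(
    Image2D(matrix(c(50, 150, 100, 100), 2, 2)), GMMask2D(matrix(1, 2, 2))),
    0.5)
  expect_error(michelsonContrast(Image2D(matrix(1, 2, 2)),
                                 GMMask2D(matrix(0, 2, 2))), "empty")
})

test_that("acquisition ranking orders by median contrast with alphabetical
           ties", {
  mk <- function(lo, hi) Image2D(matrix(c(lo, hi, lo, hi), 2, 2))
  msk <- GMMask2D(matrix(1, 2, 2))
  rec <- data.frame(slab = 1L, sample = 0:3,
                    acquisition = c("b", "b", "a", "a"),
                    image = paste0("s", 0:3), pixel_size_um = 1000,
                    section_thickness_um = 1000, qc_pass = TRUE,
                    exclude_reason = NA_character_)
  stack <- SectionStack(rec)
  images <- list(s0 = mk(0, 255), s1 = mk(0, 255),   # contrast 1
                 s2 = mk(80, 120), s3 = mk(80, 120)) # contrast 0.2
  masks <- stats::setNames(rep(list(msk), 4), paste0("s", 0:3))
  rk <- rankAcquisitions(stack, images, masks)
  expect_equal(rk$order, c("b", "a"))

  imagesTie <- list(s0 = mk(0, 255), s1 = mk(0, 255),
                    s2 = mk(0, 255), s3 = mk(0, 255))
  rkTie <- rankAcquisitions(stack, imagesTie, masks)
  expect_equal(rkTie$order, c("a", "b"))

  single <- SectionStack(rec[rec$acquisition == "a", ])
  expect_equal(rankAcquisitions(single, images, masks)$order, "a")
})

test_that("rigid registration recovers identity, shifts and rotations", {
  ph <- smallPhantom()
  m0 <- truthMask2D(ph, 40)
  id <- registerRigid2D(m0, m0)
  expect_lte(abs(id@thetaDeg), 0.1)
  expect_lte(max(abs(id@translation)), 0.2)

  ctr <- ph@center[c(1, 3)]
  sh <- applyTransform2D(m0, Rigid2D(translation = c(5, -3), center = ctr),
                         outGrid = m0, mode = "linear")
  t1 <- registerRigid2D(sh, m0)
  expect_lt(max(abs(t1@translation - c(-5, 3))), 0.5)

  rot <- applyTransform2D(m0, Rigid2D(thetaDeg = 8, center = ctr),
                          outGrid = m0, mode = "linear")
  t2 <- registerRigid2D(rot, m0)
  expect_lt(abs(t2@thetaDeg + 8), 0.5)
})

test_that("slab chaining is deterministic, keeps the central section fixed
           and recovers poses modulo the gauge", {
  ph <- smallPhantom()
  sch <- samplingScheme(coverageFraction = 1, acquisitions = "ampa",
                        dropoutProb = 0,
                        rigidJitter = list(maxRotDeg = 8, maxShiftPx = 4),
                        slabJitter = list(maxRotDeg = 0, maxShiftPx = 0),
                        warpAmplitudePx = 0)
  sl <- suppressWarnings(sliceSections(ph, sch, seed = 13))
  rec <- records(sl$stack)
  mid <- rec[order(abs(rec$sample - stats::median(rec$sample)))[1:10], ]
  mid <- mid[order(mid$sample), ]
  stack <- SectionStack(mid)
  masks <- lapply(stats::setNames(seq_len(nrow(mid)), mid$image),
                  function(i) {
    tm <- truthMask2D(ph, mid$sample[i])
    applyTransform2D(tm, sl$truth[[mid$image[i]]], outGrid = tm,
                     mode = "linear")
  })
  rig1 <- chainAlignSlab(stack, masks)
  rig2 <- chainAlignSlab(stack, masks)
  expect_identical(lapply(rig1, function(t) t@thetaDeg),
                   lapply(rig2, function(t) t@thetaDeg))

  # central section (lower middle of 10) holds the identity gauge
  cKey <- mid$image[5]
  expect_equal(rig1[[cKey]]@thetaDeg, 0)
  expect_equal(rig1[[cKey]]@translation, c(0, 0))

  # per-section pose error modulo the central-section gauge
  errs <- vapply(mid$image, function(k) {
    pk <- sl$truth[[k]]@rigid; pc <- sl$truth[[cKey]]@rigid
    E <- composeRigid2D(rig1[[k]], composeRigid2D(pk, invertRigid2D(pc)))
    th <- abs(E@thetaDeg) %% 360
    min(th, 360 - th)
  }, numeric(1))
  expect_lt(max(errs), 1)

  expect_error(chainAlignSlab(
    SectionStack(mid[0:1, ][-1, , drop = FALSE])), "non-empty|empty")
})

test_that("single-section slabs get the identity transform", {
  ph <- smallPhantom()
  rec <- records(smallSlices()$stack)[1, , drop = FALSE]
  stack <- SectionStack(rec)
  masks <- stats::setNames(list(truthMask2D(ph, rec$sample[1])), rec$image)
  rig <- chainAlignSlab(stack, masks)
  expect_equal(rig[[rec$image[1]]]@thetaDeg, 0)
  expect_equal(rig[[rec$image[1]]]@translation, c(0, 0))
})

test_that("the initial volume stacks sections at their sample planes and
           preserves intensity histograms", {
  ph <- smallPhantom()
  sch <- samplingScheme(coverageFraction = 0.5,
                        acquisitions = c("ampa", "gaba"), dropoutProb = 0,
                        rigidJitter = list(maxRotDeg = 0, maxShiftPx = 0),
                        slabJitter = list(maxRotDeg = 0, maxShiftPx = 0),
                        warpAmplitudePx = 0)
  sl <- suppressWarnings(sliceSections(ph, sch, seed = 2))
  rec <- records(sl$stack)
  rigids <- stats::setNames(rep(list(Rigid2D()), nrow(rec)), rec$image)
  resMm <- ph@truthVolume@spacing[1]
  vol <- buildInitialVolume(sl$stack, rigids, sl$images, resMm)

  # plane count forced by the sample range
  expect_equal(dim(vol@values)[2], diff(range(rec$sample)) + 1L)

  # zero-jitter stacking reproduces each section exactly at its plane
  i <- which.max(rec$sample == stats::median(rec$sample))
  i <- max(i, 2L)
  plane <- rec$sample[i] - min(rec$sample) + 1L
  img <- sl$images[[rec$image[i]]]
  expect_equal(max(abs(vol@values[, plane, ] - img@values)), 0)

  # unacquired planes are background
  gaps <- setdiff(seq_len(dim(vol@values)[2]),
                  rec$sample - min(rec$sample) + 1L)
  expect_equal(sum(vol@values[, gaps, ]), 0)

  # per-acquisition histograms preserved (same grid, zero jitter)
  for (acq in c("ampa", "gaba")) {
    sel <- rec$acquisition == acq
    pre <- unlist(lapply(sl$images[rec$image[sel]],
                         function(x) x@values))
    post <- vol@values[, rec$sample[sel] - min(rec$sample) + 1L, ]
    hPre <- hist(pre, breaks = seq(0, 256, 16), plot = FALSE)$density
    hPost <- hist(post, breaks = seq(0, 256, 16), plot = FALSE)$density
    expect_lt(mean(abs(hPre / sum(hPre) - hPost / sum(hPost))), 0.02)
  }
})
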