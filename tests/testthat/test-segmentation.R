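test_that("Otsu threshold equals an exhaustive 256-bin brute force", {
  # perfectly separable two-valued image: the bright class is exact
  img <- Image2D(matrix(c(rep(10, 40), rep(200, 60)), 10, 10))
  m <- otsuSegment(img, tissueSide = "bright")
  expect_identical(m@values, matrix(1 * (img@values == 200), 10, 10))

  withr::with_seed(8, {
    for (i in 1:50) {
      mu <- sort(runif(2, 10, 240))
      x <- matrix(c(rnorm(200, mu[1], runif(1, 2, 20)),
                    rnorm(200, mu[2], runif(1, 2, 20))), 20, 20)
      x <- pmin(pmax(x, 0), 255)
      expect_identical(otsuThreshold(x)$bin, otsuOracle(x))
    }
  })

  expect_error(otsuThreshold(matrix(7, 5, 5)), "degenerate")
})

test_that("auto side selection finds the tissue for normal and inverted
           contrast", {
  ph <- smallPhantom()
  sl <- smallSlices()
  key <- records(sl$stack)$image[3]
  img <- sl$clean[[key]]
  normal <- otsuSegment(img, "auto")
  bright <- otsuSegment(img, "bright")
  expect_equal(normal@values, bright@values)
  # inverting the full 8-bit range makes the background bright: auto must
  # pick the dark side
  inv <- Image2D(255 - img@values, img@spacing, img@origin)
  flipped <- otsuSegment(inv, "auto")
  dark <- otsuSegment(inv, "dark")
  expect_equal(flipped@values, dark@values)
})

test_that("the classical segmenter reaches Dice >= 0.90 against the truth
           GM on default-noise phantom sections", {
  ph <- smallPhantom()
  sl <- smallSlices()
  rec <- records(sl$stack)
  seg <- otsuSegmenter()
  d <- vapply(seq_len(nrow(rec)), function(i) {
    key <- rec$image[i]
    truth <- truthMask2D(ph, rec$sample[i])
    truthPert <- applyTransform2D(truth, sl$truth[[key]], outGrid = truth,
                                  mode = "nearest")
    dice(segmenterPredict(seg, sl$images[[key]]), truthPert)
  }, numeric(1))
  expect_gte(mean(d), 0.90)
})

test_that("training pairs are seed-deterministic with degenerate layer and
           skull statistics as declared", {
  ph <- smallPhantom()
  labVol <- ph@truthVolume
  rec <- synthRecipe(nImages = 4, sectionsPerVolume = 2, seed = 1)
  p1 <- synthesizeTrainingPair(labVol, rec, drawSeed = 3)
  p2 <- synthesizeTrainingPair(labVol, rec, drawSeed = 3)
  expect_identical(p1$image@values, p2$image@values)
  expect_identical(p1$labels@values, p2$labels@values)
  expect_true(all(p1$labels@values %in% c(0, 1, 2)))
  expect_true(all(p1$boundary@values %in% c(0, 1)))

  # k = 0 or 1 layers: the cortex is a single intensity class
  rec0 <- synthRecipe(layerCountRange = c(0L, 0L), noiseSdRange = c(0, 0),
                      blurSigmaRange = c(0, 0), cropFraction = 0)
  p0 <- synthesizeTrainingPair(labVol, rec0, drawSeed = 5)
  gmVals <- p0$image@values[p0$labels@values == 2]
  expect_equal(max(gmVals) - min(gmVals), 0)

  # skull present in ~50% of draws (binomial 99% band over 120 draws)
  lab <- extractPlane(labVol, 48)@values
  skulls <- withr::with_seed(21, vapply(1:120, function(i)
    recortex:::.renderTrainingPlane(lab, synthRecipe())$meta$skull,
    logical(1)))
  expect_gt(mean(skulls), 0.5 - 2.58 * sqrt(0.25 / 120))
  expect_lt(mean(skulls), 0.5 + 2.58 * sqrt(0.25 / 120))

  # layer counts uniform on {0..11} (chi-square over cheap draws)
  ks <- withr::with_seed(22, vapply(1:600, function(i)
    recortex:::.renderTrainingPlane(lab[1:20, 1:20],
                                    synthRecipe())$meta$layers,
    numeric(1)))
  expect_gt(stats::chisq.test(table(factor(ks, levels = 0:11)))$p.value,
            0.01)

  expect_error(synthesizeTrainingPair(
    Volume3D(array(1, c(4, 4, 4))), rec, 1), "cortex")
})

test_that("generateTrainingSet writes reproducible grouped pairs", {
  ph <- smallPhantom()
  tmp1 <- withr::local_tempdir(); tmp2 <- withr::local_tempdir()
  rec <- synthRecipe(nImages = 6, sectionsPerVolume = 3, seed = 4)
  idx1 <- generateTrainingSet(ph@truthVolume, rec, tmp1)
  idx2 <- generateTrainingSet(ph@truthVolume, rec, tmp2)
  expect_equal(nrow(idx1), 6)
  expect_equal(length(unique(idx1$volume)), 2)   # 6 / 3 transforms
  h1 <- tools::md5sum(file.path(tmp1, idx1$image))
  h2 <- tools::md5sum(file.path(tmp2, idx2$image))
  expect_identical(unname(h1), unname(h2))
  lab <- png::readPNG(file.path(tmp1, idx1$labels[1])) * 255
  expect_true(all(round(lab) %in% c(0, 1, 2)))
})

test_that("segmentStack falls back to Otsu on empty primary output and
           flags doubly empty sections", {
  sl <- smallSlices()
  stack <- sl$stack
  emptySeg <- Segmenter("alwaysEmpty", function(img)
    GMMask2D(matrix(0, nrow(img@values), ncol(img@values)),
             spacing = img@spacing, origin = img@origin))
  out <- segmentStack(stack, sl$images, segmenter = emptySeg,
                      fallback = otsuSegmenter())
  expect_true(all(grepl("fallback", out$log$segmenter)))
  expect_true(all(records(out$stack)$qc_pass))

  both <- segmentStack(stack, sl$images, segmenter = emptySeg,
                       fallback = emptySeg)
  expect_true(all(!records(both$stack)$qc_pass))
  expect_true(all(records(both$stack)$exclude_reason ==
                  "empty_segmentation"))

  ok <- segmentStack(stack, sl$images, segmenter = otsuSegmenter(),
                     fallback = emptySeg)
  expect_true(all(ok$log$segmenter == "otsu"))
})

test_that("segmentation evaluation aggregates per-pair Dice", {
  m1 <- randomMask(30); m2 <- randomMask(30)
  ev <- evaluateSegmentation(list(m1, m2), list(m1, m2))
  expect_equal(ev$mean, 1); expect_equal(ev$sd, 0)

  disjoint <- GMMask2D(1 - m1@values)
  ev2 <- evaluateSegmentation(list(m1, m2), list(m1, disjoint))
  expect_equal(ev2$perSection$dice[1], 1)
  expect_equal(ev2$perSection$dice[2], dice(m2, disjoint))
  expect_error(evaluateSegmentation(list(m1), list(m1, m2)), "unpaired")

  # resized evaluation still agrees with the dice oracle on the common grid
  ev3 <- evaluateSegmentation(list(m1), list(m2), downsampleTo = c(30, 30))
  expect_equal(ev3$perSection$dice[1], diceOracle(m1@values, m2@values))
})
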