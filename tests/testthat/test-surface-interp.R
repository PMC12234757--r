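test_that("depth surfaces interpolate linearly between the WM and pial
           borders", {
  ph <- smallPhantom()
  ds <- generateDepthSurfaces(ph@wmMesh, ph@pialMesh, 18)
  expect_length(ds@meshes, 20)
  expect_identical(ds@meshes[[1]]@vertices, ph@wmMesh@vertices)
  expect_identical(ds@meshes[[20]]@vertices, ph@pialMesh@vertices)

  one <- generateDepthSurfaces(ph@wmMesh, ph@pialMesh, 1)
  expect_equal(one@meshes[[2]]@vertices,
               (ph@wmMesh@vertices + ph@pialMesh@vertices) / 2)

  badTri <- ph@pialMesh
  badTri@triangles <- badTri@triangles[-1, , drop = FALSE]
  expect_error(generateDepthSurfaces(ph@wmMesh, badTri, 1), "topology")
})

test_that("mesh upsampling inserts the exact barycentric lattice and never
           exceeds the target edge length", {
  r <- 2
  eq <- function(edge) SurfaceMesh(rbind(c(0, 0, 0), c(edge, 0, 0),
                                         c(edge / 2, edge * sqrt(3) / 2, 0)),
                                   matrix(1:3, 1))
  # edge exactly r: alpha, beta in {0, 0.5, 1} -> 6 points, 4 sub-triangles
  up <- upsampleMesh(eq(r), r = r)
  expect_equal(nrow(up@vertices), 6)
  expect_equal(nrow(up@triangles), 4)
  # original vertices preserved at their indices
  expect_equal(up@vertices[1:3, ], eq(r)@vertices)

  # short edges: no interior grid points, mesh unchanged
  same <- upsampleMesh(eq(0.4 * r), r = r)
  expect_equal(nrow(same@vertices), 3)

  withr::with_seed(10, {
    for (i in 1:30) {
      v <- matrix(rnorm(9), 3) * runif(1, 0.5, 4)
      m <- tryCatch(SurfaceMesh(v, matrix(1:3, 1)),
                    error = function(e) NULL)
      if (is.null(m)) next
      up <- upsampleMesh(m, r = 1)
      e <- meshEdges(up)
      len <- sqrt(rowSums((up@vertices[e[, 1], , drop = FALSE] -
                           up@vertices[e[, 2], , drop = FALSE])^2))
      expect_lte(max(len), 1)
      # every inserted point satisfies the barycentric constraints:
      # solve for (alpha, beta) in the source triangle
      A <- v[1, ]; B <- v[2, ]; C <- v[3, ]
      M <- cbind(B - A, C - A)
      ab <- t(apply(up@vertices, 1, function(p) qr.solve(M, p - A)))
      expect_true(all(ab >= -1e-9) && all(rowSums(ab) <= 1 + 1e-9))
    }
  })
})

test_that("upsampling preserves shared topology across a depth set", {
  ph <- smallPhantom()
  n <- upsampleOrder(ph@pialMesh, 2)
  upW <- upsampleMesh(ph@wmMesh, n = n)
  upP <- upsampleMesh(ph@pialMesh, n = n)
  expect_identical(upW@triangles, upP@triangles)
  # depth linearity survives subdivision: the upsampled mid-surface equals
  # the midpoint of the upsampled borders
  mid <- SurfaceMesh((ph@wmMesh@vertices + ph@pialMesh@vertices) / 2,
                     ph@wmMesh@triangles)
  upM <- upsampleMesh(mid, n = n)
  expect_equal(upM@vertices, (upW@vertices + upP@vertices) / 2,
               tolerance = 1e-9)
})

test_that("sphere inflation projects radially, preserves topology and
           reports distortion", {
  s <- icosphereMesh(2, radius = 5, center = c(1, 2, 3))
  infl <- inflateToSphere(s, center = c(1, 2, 3))
  expect_equal(sqrt(rowSums(infl@vertices^2)), rep(1, nrow(infl@vertices)),
               tolerance = 1e-9)
  expect_identical(infl@triangles, s@triangles)
  expect_lt(attr(infl, "distortion"), 1e-9)   # a sphere inflates exactly

  ph <- smallPhantom()
  mid <- SurfaceMesh((ph@wmMesh@vertices + ph@pialMesh@vertices) / 2,
                     ph@wmMesh@triangles)
  sm <- inflateToSphere(mid, center = ph@center)
  # no triangle flips: all spherical orientations consistent
  a <- sm@vertices[sm@triangles[, 1], ]
  n <- recortex:::.rowCross(sm@vertices[sm@triangles[, 2], ] - a,
                            sm@vertices[sm@triangles[, 3], ] - a)
  cen <- (a + sm@vertices[sm@triangles[, 2], ] +
          sm@vertices[sm@triangles[, 3], ]) / 3
  expect_true(all(rowSums(n * cen) > 0) || all(rowSums(n * cen) < 0))

  # an externally supplied sphere passes through unchanged
  expect_identical(inflateToSphere(sm), sm)
})

test_that("spherical interpolation is exact at known vertices, bounded by
           the known range, and recovers ambient-linear fields", {
  dense <- icosphereMesh(3)
  nV <- nrow(dense@vertices)
  withr::with_seed(14, known <- sample(nV, 200))
  a <- c(0.4, -0.2, 0.8)
  vals <- rep(NA_real_, nV)
  vals[known] <- dense@vertices[known, ] %*% a
  f <- VertexField(vals, seq_len(nV) %in% known)
  out <- interpolateSphere(dense, f)
  expect_true(all(out@known))
  expect_equal(out@values[known], vals[known])   # known values untouched
  expect_gte(min(out@values), min(vals[known]) - 1e-9)
  expect_lte(max(out@values), max(vals[known]) + 1e-9)
  true <- as.numeric(dense@vertices %*% a)
  expect_gte(stats::cor(out@values[-known], true[-known])^2, 0.99)

  # constant field propagates exactly
  fc <- VertexField(ifelse(seq_len(nV) %in% known, 3.3, NA_real_))
  outc <- interpolateSphere(dense, fc)
  expect_equal(outc@values, rep(3.3, nV), tolerance = 1e-12)

  few <- VertexField(c(1, 2, rep(NA_real_, nV - 2)))
  expect_error(interpolateSphere(dense, few), "at least 3")
})

test_that("section-to-vertex sampling respects the capture window and the
           phantom forward model", {
  ph <- smallPhantom()
  sl <- smallSlices()
  stack <- sl$stack
  rec <- records(stack)
  chainsTruth <- sl$truth
  ds0 <- generateDepthSurfaces(ph@wmMesh, ph@pialMesh, 8)
  n <- upsampleOrder(ph@pialMesh, 2 * 1)
  ds <- DepthSurfaceSet(lapply(ds0@meshes, upsampleMesh, n = n), ds0@depths)

  idChains <- stats::setNames(rep(list(TransformChain()), nrow(rec)),
                              rec$image)
  fs <- sampleSectionsToVertices(stack, idChains, ds, sl$clean, "ampa")
  thick <- rec$section_thickness_um[1] / 1000
  planes <- rec$sample[rec$acquisition == "ampa"] * thick
  for (k in c(1, 5)) {
    v <- ds@meshes[[k]]@vertices
    known <- fs[[k]]@known
    dmin <- vapply(v[, 2], function(y) min(abs(y - planes)), numeric(1))
    expect_true(all(dmin[known] <= thick / 2 + 1e-9))
    expect_true(all(!known[dmin > thick / 2 + 1e-9]))
  }

  # sampled values follow the truth model at mid-depth vertices (value =
  # offset + gain * density; clean sections carry no additive noise, so
  # the residual is nearest-pixel quantisation plus border contamination)
  k <- 5
  v <- ds@meshes[[k]]@vertices
  known <- fs[[k]]@known
  spec <- ph@fieldSpecs[["ampa"]]
  trueI <- spec$offset + spec$gain * truthFieldValues(ph, "ampa",
                                                      v[known, ])
  err <- abs(fs[[k]]@values[known] - trueI)
  expect_lt(stats::median(err), 5)

  expect_warning(sampleSectionsToVertices(stack, chainsTruth, ds,
                                          sl$images, "nonexistent"),
                 "no acquired sections")
})

test_that("projection to volume averages vertices per voxel and fills gaps
           linearly", {
  # two vertices in one voxel average; constant field round trip is exact
  mesh <- SurfaceMesh(rbind(c(1.1, 1, 1), c(0.9, 1, 1), c(1, 3, 1),
                            c(5, 5, 5)),
                      matrix(c(1, 2, 3), 1))
  ds <- DepthSurfaceSet(list(mesh, mesh), c(0, 1))
  f1 <- VertexField(c(10, 20, 7, 7))
  f0 <- VertexField(rep(0, 4), rep(FALSE, 4))
  grid <- list(dim = c(8L, 8L, 8L), spacing = c(1, 1, 1),
               origin = c(0, 0, 0))
  cortex <- GMMask3D(array(1, c(8, 8, 8)))
  vol <- projectToVolume(list(f1, f0), ds, grid, cortex, fill = FALSE)
  expect_equal(vol@values[2, 2, 2], 15)   # mean of 10 and 20
  expect_equal(vol@values[2, 4, 2], 7)

  # 1D gap: Laplacian fill reduces to linear interpolation
  lineMesh <- SurfaceMesh(rbind(c(1, 1, 1), c(1, 6, 1), c(4, 4, 4)),
                          matrix(1:3, 1))
  dsl <- DepthSurfaceSet(list(lineMesh, lineMesh), c(0, 1))
  fl <- VertexField(c(0, 10, NA), c(TRUE, TRUE, FALSE))
  tube <- array(0, c(8, 8, 8)); tube[2, 2:7, 2] <- 1
  volF <- projectToVolume(list(fl, fl), dsl, grid,
                          GMMask3D(tube), fill = TRUE)
  expect_equal(volF@values[2, 2:7, 2], seq(0, 10, by = 2),
               tolerance = 0.05)
})
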