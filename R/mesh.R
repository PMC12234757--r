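# Triangulated-surface machinery: icosphere construction, regular
# barycentric upsampling with a pattern shared across depth surfaces,
# depth-surface generation, radial sphere inflation, and rasterization of
# the cortical ribbon into a voxel mask.

#' Icosphere mesh
#'
#' Repeatedly subdivides an icosahedron and projects to the sphere, giving a
#' near-uniform triangulation used as the base topology for phantom
#' surfaces.
#'
#' @param subdiv number of 4-to-1 subdivision rounds (0 = icosahedron).
#' @param radius sphere radius (mm).
#' @param center numeric(3) sphere centre (mm).
#' @return a [SurfaceMesh] with outward-oriented triangles.
#' @export
icosphereMesh <- function(subdiv = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    sub <- .subdivideTriangles(v, f, 2L)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$triangles
  }
  m <- SurfaceMesh(sweep(v * radius, 2, center, `+`), f,
                   spaceTag = "reference")
  .orientOutward(m, center)
}

# Flip triangles so all normals point away from `center`.
.orientOutward <- function(mesh, center) {
  v <- mesh@vertices; f <- mesh@triangles
  a <- v[f[, 1], , drop = FALSE]
  n <- .rowCross(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  cen <- (a + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
  flip <- rowSums(n * sweep(cen, 2, center)) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  SurfaceMesh(v, f, spaceTag = mesh@spaceTag)
}

#' Unique undirected edges of a mesh
#' @param mesh a [SurfaceMesh].
#' @return 2-column integer matrix of vertex index pairs (lower index
#'   first).
#' @export
meshEdges <- function(mesh) {
  f <- mesh@triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency list of a mesh
#' @param mesh a [SurfaceMesh].
#' @return list; element i holds the neighbour vertex indices of vertex i.
#' @export
meshAdjacency <- function(mesh) {
  e <- meshEdges(mesh)
  n <- nrow(mesh@vertices)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = 1:n))
  lapply(adj, unique)
}

# Regular order-n barycentric subdivision of every triangle. Lattice points
# P(i,j) = A + (i/n) AB + (j/n) AC with i, j >= 0, i + j <= n. Original
# vertices keep their indices; edge points are shared between the two
# triangles of an edge via canonical keys; positions are barycentric-linear
# in the corner vertices, so applying the same order to meshes of shared
# topology yields vertex-for-vertex corresponding results.
.subdivideTriangles <- function(v, f, n) {
  if (n <= 1L) return(list(vertices = v, triangles = f))
  nT <- nrow(f)
  ij <- expand.grid(i = 0:n, j = 0:n)
  ij <- ij[ij$i + ij$j <= n, ]
  nL <- nrow(ij)
  tri <- rep(seq_len(nT), each = nL)
  i <- rep(ij$i, times = nT); j <- rep(ij$j, times = nT)
  A <- f[tri, 1]; B <- f[tri, 2]; C <- f[tri, 3]
  # canonical identity of each lattice point
  key <- character(length(i))
  corner <- i == 0 & j == 0
  key[corner] <- paste0("v", A[corner])
  cb <- i == n; key[cb] <- paste0("v", B[cb])
  cc <- j == n; key[cc] <- paste0("v", C[cc])
  eAB <- j == 0 & i > 0 & i < n
  eAC <- i == 0 & j > 0 & j < n
  eBC <- i + j == n & i > 0 & j > 0
  edgeKey <- function(p, q, t) {
    lo <- pmin(p, q); hi <- pmax(p, q)
    tt <- ifelse(p < q, t, n - t)
    paste0("e", lo, "_", hi, "_", tt)
  }
  key[eAB] <- edgeKey(A[eAB], B[eAB], i[eAB])
  key[eAC] <- edgeKey(A[eAC], C[eAC], j[eAC])
  key[eBC] <- edgeKey(B[eBC], C[eBC], j[eBC])
  inter <- !(corner | cb | cc | eAB | eAC | eBC)
  key[inter] <- paste0("t", tri[inter], "_", i[inter], "_", j[inter])

  # stable global ids: original vertices first, then new points
  origKey <- paste0("v", seq_len(nrow(v)))
  allKey <- c(origKey, setdiff(unique(key), origKey))
  id <- match(key, allKey)

  w1 <- 1 - (i + j) / n; w2 <- i / n; w3 <- j / n
  verts <- matrix(0, length(allKey), 3)
  pos <- w1 * v[A, , drop = FALSE] + w2 * v[B, , drop = FALSE] +
    w3 * v[C, , drop = FALSE]
  verts[id, ] <- pos  # duplicates write identical coordinates
  verts[seq_len(nrow(v)), ] <- v

  # lattice index lookup per triangle: local index of (i, j)
  lidx <- matrix(0L, n + 1, n + 1)
  lidx[cbind(ij$i + 1L, ij$j + 1L)] <- seq_len(nL)
  glob <- matrix(id, nL, nT)  # local point x triangle
  up <- dn <- NULL
  for (ii in 0:(n - 1)) for (jj in 0:(n - 1 - ii)) {
    up <- rbind(up, c(lidx[ii + 1, jj + 1], lidx[ii + 2, jj + 1],
                      lidx[ii + 1, jj + 2]))
    if (ii + jj <= n - 2)
      dn <- rbind(dn, c(lidx[ii + 2, jj + 1], lidx[ii + 2, jj + 2],
                        lidx[ii + 1, jj + 2]))
  }
  cells <- rbind(up, dn)
  triOut <- do.call(rbind, lapply(seq_len(nT), function(t)
    matrix(glob[cells, t], ncol = 3)))
  list(vertices = verts, triangles = triOut)
}

#' Upsampling order needed to reach a target resolution
#'
#' The number of equal increments each triangle edge is cut into so that the
#' longest subdivided edge is at most half the target resolution step `0.5 r`
#' per increment: `n = max(1, ceil(max edge length / (0.5 r)))`. A single
#' global order keeps the subdivided mesh crack-free and lets depth surfaces
#' and spheres share one subdivision pattern.
#'
#' @param mesh a [SurfaceMesh] (use the mesh with the longest edges of a
#'   shared-topology family, typically the pial surface).
#' @param r target resolution (mm), > 0.
#' @return integer subdivision order.
#' @export
upsampleOrder <- function(mesh, r) {
  stopifnot(r > 0)
  e <- meshEdges(mesh)
  len <- sqrt(rowSums((mesh@vertices[e[, 1], , drop = FALSE] -
                       mesh@vertices[e[, 2], , drop = FALSE])^2))
  max(1L, as.integer(ceiling(max(len) / (0.5 * r))))
}

#' Upsample a mesh by regular barycentric subdivision
#'
#' Inserts the lattice points `P = A + alpha AB + beta AC` with `alpha`,
#' `beta` and `alpha + beta` in \[0, 1\] on an even grid inside every
#' triangle, then re-triangulates by regular subdivision. Original vertices
#' are preserved (same indices); after upsampling at order
#' [upsampleOrder()] the maximum neighbour distance is at most `r`.
#'
#' @param mesh a [SurfaceMesh].
#' @param r target resolution (mm); ignored when `n` is given.
#' @param n explicit subdivision order (to reuse one pattern across a
#'   shared-topology family).
#' @return the upsampled [SurfaceMesh] (same space tag; sphere-space meshes
#'   are re-normalised to the unit sphere).
#' @export
upsampleMesh <- function(mesh, r = NULL, n = NULL) {
  if (is.null(n)) {
    if (is.null(r)) stop("upsampleMesh: give a target resolution r or an order n")
    n <- upsampleOrder(mesh, r)
  }
  sub <- .subdivideTriangles(mesh@vertices, mesh@triangles, as.integer(n))
  v <- sub$vertices
  if (mesh@spaceTag == "sphere") v <- v / sqrt(rowSums(v^2))
  SurfaceMesh(v, sub$triangles, spaceTag = mesh@spaceTag)
}

#' Generate evenly spaced cortical depth surfaces
#'
#' Vertex i of the surface at fractional depth d is
#' `(1 - d) wm_i + d pial_i`; depths are evenly spaced over \[0, 1\], so the
#' WM-GM and pial borders are included and `nIntermediate` surfaces span the
#' cortex between them.
#'
#' @param wm,pial shared-topology [SurfaceMesh]es (WM-GM and pial borders).
#' @param nIntermediate number of intermediate surfaces (18 gives 20 meshes).
#' @return a [DepthSurfaceSet] of `nIntermediate + 2` meshes.
#' @export
generateDepthSurfaces <- function(wm, pial, nIntermediate = 18L) {
  if (!identical(wm@triangles, pial@triangles) ||
      nrow(wm@vertices) != nrow(pial@vertices))
    stop("generateDepthSurfaces: meshes must share topology")
  depths <- seq(0, 1, length.out = nIntermediate + 2L)
  meshes <- lapply(depths, function(d)
    SurfaceMesh((1 - d) * wm@vertices + d * pial@vertices, wm@triangles,
                spaceTag = wm@spaceTag))
  DepthSurfaceSet(meshes, depths)
}

#' Inflate a cortical mesh to the unit sphere
#'
#' Radial projection about the mesh centroid. This is exact for the
#' star-shaped phantom surfaces; real cortical meshes are not star-shaped,
#' so externally computed spheres (FreeSurfer-style) must be supplied
#' instead and are validated and passed through.
#'
#' @param mesh a [SurfaceMesh] to inflate, or an externally supplied
#'   sphere-space mesh (returned unchanged after validation).
#' @param center projection centre; default the vertex centroid.
#' @return a unit-sphere [SurfaceMesh]; the relative inter-vertex distance
#'   distortion is attached as attribute `"distortion"`.
#' @export
inflateToSphere <- function(mesh, center = NULL) {
  if (mesh@spaceTag == "sphere") return(mesh)
  if (is.null(center)) center <- colMeans(mesh@vertices)
  d <- sweep(mesh@vertices, 2, center)
  rad <- sqrt(rowSums(d^2))
  if (any(rad == 0)) stop("inflateToSphere: vertex at projection centre")
  s <- SurfaceMesh(d / rad, mesh@triangles, spaceTag = "sphere")
  # orientation consistency: radial projection of a star-shaped surface
  # never flips triangles; a flip means the mesh was not star-shaped
  a <- s@vertices[s@triangles[, 1], , drop = FALSE]
  n <- .rowCross(s@vertices[s@triangles[, 2], , drop = FALSE] - a,
                 s@vertices[s@triangles[, 3], , drop = FALSE] - a)
  cen <- (a + s@vertices[s@triangles[, 2], , drop = FALSE] +
          s@vertices[s@triangles[, 3], , drop = FALSE]) / 3
  sgn <- sign(rowSums(n * cen))
  if (length(unique(sgn[sgn != 0])) > 1)
    stop("inflateToSphere: mesh is not star-shaped about the centre; ",
         "supply externally inflated sphere meshes instead")
  # distance distortion: per-edge ratio (sphere / native), relative spread
  e <- meshEdges(mesh)
  ln <- sqrt(rowSums((mesh@vertices[e[, 1], ] - mesh@vertices[e[, 2], ])^2))
  ls <- sqrt(rowSums((s@vertices[e[, 1], ] - s@vertices[e[, 2], ])^2))
  ratio <- ls / ln
  attr(s, "distortion") <- stats::sd(ratio) / mean(ratio)
  s
}

#' Rasterize the cortical ribbon between two surfaces into a voxel mask
#'
#' Sweeps densely over cortical depth, upsamples every depth surface to the
#' target resolution, and marks each voxel containing at least one sampled
#' surface point.
#'
#' @param wm,pial shared-topology border meshes.
#' @param resMm output voxel size (mm).
#' @param grid optional target grid (a [Volume3D]-like object to copy the
#'   grid from); default: the padded bounding box of the pial mesh.
#' @param depthStepMm depth sweep step (default `resMm / 2`).
#' @return a binary [GMMask3D].
#' @export
rasterizeSurfacesToGM <- function(wm, pial, resMm, grid = NULL,
                                  depthStepMm = resMm / 2) {
  if (!identical(wm@triangles, pial@triangles) ||
      nrow(wm@vertices) != nrow(pial@vertices))
    stop("rasterizeSurfacesToGM: meshes must share topology")
  n <- upsampleOrder(pial, resMm)
  wmU <- upsampleMesh(wm, n = n)
  pialU <- upsampleMesh(pial, n = n)
  thick <- sqrt(rowSums((pialU@vertices - wmU@vertices)^2))
  nD <- max(2L, as.integer(ceiling(max(thick) / depthStepMm)) + 1L)
  depths <- seq(0, 1, length.out = nD)
  if (is.null(grid)) {
    lo <- apply(pialU@vertices, 2, min) - resMm
    hi <- apply(pialU@vertices, 2, max) + resMm
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / resMm)))
    grid <- list(dim = dims, spacing = rep(resMm, 3), origin = lo + resMm / 2)
  } else if (is(grid, "Volume3D")) {
    grid <- list(dim = dim(grid@values), spacing = grid@spacing,
                 origin = grid@origin)
  }
  arr <- array(0, grid$dim)
  for (d in depths) {
    p <- (1 - d) * wmU@vertices + d * pialU@vertices
    ix <- round(.worldToIndex(p[, 1], grid$origin[1], grid$spacing[1]))
    iy <- round(.worldToIndex(p[, 2], grid$origin[2], grid$spacing[2]))
    iz <- round(.worldToIndex(p[, 3], grid$origin[3], grid$spacing[3]))
    ok <- ix >= 1 & ix <= grid$dim[1] & iy >= 1 & iy <= grid$dim[2] &
      iz >= 1 & iz <= grid$dim[3]
    arr[cbind(ix[ok], iy[ok], iz[ok])] <- 1
  }
  GMMask3D(arr, spacing = grid$spacing, origin = grid$origin)
}
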