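# Piecewise-linear interpolation of sparse vertex data over the unit
# sphere. The triangulation of the known vertices is their 3D convex hull
# (for points on a sphere the hull is exactly the spherical Delaunay
# triangulation); a missing vertex takes the barycentric interpolant of the
# hull triangle its radial ray passes through. Weights are convex, so the
# interpolant never leaves the range of the known values.

# Randomized incremental 3D convex hull with two-way conflict lists
# (face -> unprocessed points that see it, point -> faces it sees).
# pts: n x 3, assumed full-dimensional (true for >= 4 sphere points).
# Returns an m x 3 matrix of outward-oriented triangles (1-based indices).
.convhull3 <- function(pts) {
  n <- nrow(pts)
  if (n < 4) stop("convhull3: need at least 4 points")
  eps <- 1e-10 * max(abs(pts), 1)

  # initial tetrahedron: 4 non-coplanar points
  i1 <- 1L
  d <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d)
  ab <- pts[i2, ] - pts[i1, ]
  cr <- .rowCross(matrix(ab, n, 3, byrow = TRUE), sweep(pts, 2, pts[i1, ]))
  i3 <- which.max(rowSums(cr^2))
  nrm <- .rowCross(matrix(ab, 1), matrix(pts[i3, ] - pts[i1, ], 1))
  h <- abs(as.numeric(sweep(pts, 2, pts[i1, ]) %*% t(nrm)))
  i4 <- which.max(h)
  if (h[i4] <= eps) stop("convhull3: points are coplanar")
  init <- c(i1, i2, i3, i4)
  inside0 <- colMeans(pts[init, , drop = FALSE])

  cap <- max(64L, 8L * n)
  faceVert <- matrix(0L, cap, 3)
  faceNorm <- matrix(0, cap, 3)
  faceOff <- numeric(cap)
  alive <- logical(cap)
  fconf <- vector("list", cap)   # face -> points
  nFace <- 0L
  pconf <- vector("list", n)     # point -> faces
  edgeFace <- new.env(hash = TRUE)  # directed edge "a_b" -> newest face

  grow <- function() {
    cap2 <- 2L * nrow(faceVert)
    faceVert <<- rbind(faceVert, matrix(0L, cap2 - nrow(faceVert), 3))
    faceNorm <<- rbind(faceNorm, matrix(0, cap2 - nrow(faceNorm), 3))
    length(faceOff) <<- cap2; length(alive) <<- cap2
    length(fconf) <<- cap2
    alive[is.na(alive)] <<- FALSE
  }

  addFace <- function(a, b, c, cand) {
    p <- pts[a, ]; q <- pts[b, ]; r <- pts[c, ]
    nv <- c((q[2] - p[2]) * (r[3] - p[3]) - (q[3] - p[3]) * (r[2] - p[2]),
            (q[3] - p[3]) * (r[1] - p[1]) - (q[1] - p[1]) * (r[3] - p[3]),
            (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
    if (sum(nv * (inside0 - p)) > 0) {
      tmp <- b; b <- c; c <- tmp; nv <- -nv
    }
    off <- sum(nv * p)
    if (nFace + 1L > nrow(faceVert)) grow()
    nFace <<- nFace + 1L
    f <- nFace
    faceVert[f, ] <<- c(a, b, c)
    faceNorm[f, ] <<- nv
    faceOff[f] <<- off
    alive[f] <<- TRUE
    if (length(cand)) {
      see <- cand[(pts[cand, , drop = FALSE] %*% nv) - off > eps]
      fconf[[f]] <<- see
      for (s in see) pconf[[s]] <<- c(pconf[[s]], f)
    } else fconf[[f]] <<- integer(0)
    assign(paste0(a, "_", b), f, envir = edgeFace)
    assign(paste0(b, "_", c), f, envir = edgeFace)
    assign(paste0(c, "_", a), f, envir = edgeFace)
    f
  }

  rest <- setdiff(seq_len(n), init)
  addFace(init[1], init[2], init[3], rest)
  addFace(init[1], init[2], init[4], rest)
  addFace(init[1], init[3], init[4], rest)
  addFace(init[2], init[3], init[4], rest)
  done <- rep(FALSE, n); done[init] <- TRUE

  for (p in rest) {
    vis <- pconf[[p]]
    vis <- vis[alive[vis]]
    pconf[p] <- list(integer(0))
    done[p] <- TRUE
    if (!length(vis)) next
    fv <- faceVert[vis, , drop = FALSE]
    edges <- cbind(c(fv[, 1], fv[, 2], fv[, 3]),
                   c(fv[, 2], fv[, 3], fv[, 1]))
    ek <- paste(edges[, 1], edges[, 2])
    rk <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(ek %in% rk), , drop = FALSE]
    # candidate pool: points seen by the deleted faces or by the alive
    # faces just across the horizon (needed for correct conflict updates)
    acrossIds <- unique(vapply(seq_len(nrow(horizon)), function(e)
      get0(paste0(horizon[e, 2], "_", horizon[e, 1]), envir = edgeFace,
           ifnotfound = 0L), integer(1)))
    acrossIds <- acrossIds[acrossIds > 0 & alive[acrossIds]]
    pool <- unique(c(unlist(fconf[vis], use.names = FALSE),
                     unlist(fconf[acrossIds], use.names = FALSE)))
    pool <- pool[!done[pool]]
    alive[vis] <- FALSE
    fconf[vis] <- list(integer(0))
    for (e in seq_len(nrow(horizon)))
      addFace(horizon[e, 1], horizon[e, 2], p, pool)
  }
  faceVert[which(alive[seq_len(nFace)]), , drop = FALSE]
}

#' Triangulate points on the unit sphere
#'
#' Convex hull of unit vectors, which coincides with the spherical Delaunay
#' triangulation.
#'
#' @param dirs n x 3 matrix of unit vectors (n >= 4 for a full
#'   triangulation; exactly 3 non-collinear points yield the single
#'   triangle).
#' @return m x 3 integer matrix of outward-oriented triangles.
#' @export
sphereTriangulation <- function(dirs) {
  dirs <- as.matrix(dirs)
  if (nrow(dirs) == 3) return(matrix(1:3, 1))
  .convhull3(dirs)
}

# Bucket grid over unit vectors for nearest-point candidate lookup.
.dirBuckets <- function(dirs, cell) {
  key <- paste(floor(dirs[, 1] / cell), floor(dirs[, 2] / cell),
               floor(dirs[, 3] / cell))
  split(seq_len(nrow(dirs)), key)
}

# nearest known direction for every query, grouped by grid cell so the
# inner distance computations are small dense blocks
.nearestDir <- function(query, dirs, buckets, cell) {
  n <- nrow(query)
  out <- integer(n)
  qkey <- paste(floor(query[, 1] / cell), floor(query[, 2] / cell),
                floor(query[, 3] / cell))
  qcells <- split(seq_len(n), qkey)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (ck in names(qcells)) {
    qi <- qcells[[ck]]
    cc <- as.integer(strsplit(ck, " ")[[1]])
    keys <- paste(cc[1] + off$dx, cc[2] + off$dy, cc[3] + off$dz)
    cand <- unlist(buckets[keys], use.names = FALSE)
    r <- 1L
    while (!length(cand) && r <= 4L) {
      r <- r + 1L
      rng <- (-r):r
      o2 <- expand.grid(dx = rng, dy = rng, dz = rng)
      keys <- paste(cc[1] + o2$dx, cc[2] + o2$dy, cc[3] + o2$dz)
      cand <- unlist(buckets[keys], use.names = FALSE)
    }
    if (!length(cand)) {
      for (i in qi) out[i] <- which.min(
        (dirs[, 1] - query[i, 1])^2 + (dirs[, 2] - query[i, 2])^2 +
        (dirs[, 3] - query[i, 3])^2)
      next
    }
    # block distance: |q|^2 and |d|^2 are constant on the unit sphere, so
    # nearest = max dot product
    dp <- query[qi, , drop = FALSE] %*% t(dirs[cand, , drop = FALSE])
    out[qi] <- cand[max.col(dp, ties.method = "first")]
  }
  out
}

#' Spherical piecewise-linear interpolation of a sparse vertex field
#'
#' Builds the spherical triangulation of the known vertices, then gives
#' every missing vertex the barycentric interpolant of the triangle its
#' direction falls in. Known vertices are returned unchanged; the output is
#' bounded by the range of the known values (weights are convex).
#'
#' @param sphereMesh a sphere-space [SurfaceMesh] whose vertex order matches
#'   the field.
#' @param field a [VertexField] with at least 3 known, non-collinear
#'   vertices.
#' @return a complete [VertexField] (all vertices known).
#' @export
interpolateSphere <- function(sphereMesh, field) {
  stopifnot(nrow(sphereMesh@vertices) == length(field@values))
  known <- which(field@known)
  if (length(known) < 3)
    stop("interpolateSphere: need at least 3 known vertices")
  out <- field@values
  miss <- which(!field@known)
  if (!length(miss)) return(VertexField(out, rep(TRUE, length(out))))
  P <- sphereMesh@vertices[known, , drop = FALSE]
  P <- P / sqrt(rowSums(P^2))
  tris <- sphereTriangulation(P)
  Q <- sphereMesh@vertices[miss, , drop = FALSE]
  Q <- Q / sqrt(rowSums(Q^2))
  w <- .sphereBary(Q, P, tris)
  vals <- field@values[known]
  out[miss] <- w$w1 * vals[w$t[, 1]] + w$w2 * vals[w$t[, 2]] +
    w$w3 * vals[w$t[, 3]]
  VertexField(out, rep(TRUE, length(out)))
}

# Barycentric weights of query directions within a spherical triangulation.
# For query u and triangle (p1,p2,p3) the radial projection onto the
# triangle plane has barycentric coordinates w_i = dot(r_i, u) / det with
# r1 = p2 x p3 etc.; the containing triangle has all w_i >= 0. Candidate
# triangles come from the 2-ring of the nearest triangulation vertex, with
# a brute-force fallback. Weights are clipped to >= 0 and renormalised.
.sphereBary <- function(Q, P, tris) {
  nT <- nrow(tris)
  p1 <- P[tris[, 1], , drop = FALSE]
  p2 <- P[tris[, 2], , drop = FALSE]
  p3 <- P[tris[, 3], , drop = FALSE]
  r1 <- .rowCross(p2, p3); r2 <- .rowCross(p3, p1); r3 <- .rowCross(p1, p2)
  det <- rowSums(p1 * r1)
  # orient so det > 0
  flip <- det < 0
  r1[flip, ] <- -r1[flip, ]; r2[flip, ] <- -r2[flip, ]; r3[flip, ] <- -r3[flip, ]
  det <- abs(det)
  det[det == 0] <- .Machine$double.eps

  # vertex -> incident triangles
  inc <- split(rep(seq_len(nT), 3), c(tris[, 1], tris[, 2], tris[, 3]))
  # vertex -> ring vertices
  adjV <- split(c(tris[, 2], tris[, 3], tris[, 1], tris[, 3], tris[, 1],
                  tris[, 2]),
                c(tris[, 1], tris[, 1], tris[, 2], tris[, 2], tris[, 3],
                  tris[, 3]))
  adjV <- lapply(adjV, unique)

  cell <- max(0.05, 4 / sqrt(max(nrow(P), 1)))
  buckets <- .dirBuckets(P, cell)
  nearest <- .nearestDir(Q, P, buckets, cell)

  nQ <- nrow(Q)
  ti <- integer(nQ); w1 <- w2 <- w3 <- numeric(nQ)
  tol <- -1e-9

  # candidate (query, triangle) pairs: triangles incident to the 2-ring of
  # the nearest triangulation vertex, tested in one vectorised pass
  ring2 <- lapply(seq_len(nrow(P)), function(v) {
    r1v <- adjV[[as.character(v)]]
    if (is.null(r1v)) return(integer(0))
    unique(c(v, r1v, unlist(adjV[as.character(r1v)], use.names = FALSE)))
  })
  candOf <- lapply(ring2, function(r)
    unique(unlist(inc[as.character(r)], use.names = FALSE)))
  candList <- candOf[nearest]
  nCand <- lengths(candList)
  qi <- rep(seq_len(nQ), nCand)
  tj <- unlist(candList, use.names = FALSE)
  a <- (r1[tj, 1] * Q[qi, 1] + r1[tj, 2] * Q[qi, 2] +
        r1[tj, 3] * Q[qi, 3]) / det[tj]
  b <- (r2[tj, 1] * Q[qi, 1] + r2[tj, 2] * Q[qi, 2] +
        r2[tj, 3] * Q[qi, 3]) / det[tj]
  cc <- (r3[tj, 1] * Q[qi, 1] + r3[tj, 2] * Q[qi, 2] +
         r3[tj, 3] * Q[qi, 3]) / det[tj]
  s <- a + b + cc
  inside <- a >= tol & b >= tol & cc >= tol & s > 0
  minw <- pmin(a, b, cc) / pmax(s, 1e-12)
  ord <- order(qi, -inside, -minw)
  first <- ord[!duplicated(qi[ord])]
  hit <- inside[first]
  ti[qi[first]] <- tj[first]
  sw <- pmax(a[first], 0) + pmax(b[first], 0) + pmax(cc[first], 0)
  w1[qi[first]] <- pmax(a[first], 0) / sw
  w2[qi[first]] <- pmax(b[first], 0) / sw
  w3[qi[first]] <- pmax(cc[first], 0) / sw

  # queries the local candidates missed: brute force over all triangles
  missQ <- qi[first][!hit]
  for (i in missQ) {
    u <- Q[i, ]
    av <- (r1 %*% u) / det; bv <- (r2 %*% u) / det; cv <- (r3 %*% u) / det
    sv <- av + bv + cv
    ok <- which(av >= tol & bv >= tol & cv >= tol & sv > 0)
    j <- if (length(ok)) ok[1] else
      which.max(pmin(av, bv, cv) / pmax(sv, 1e-12))
    wts <- pmax(c(av[j], bv[j], cv[j]), 0)
    wts <- wts / sum(wts)
    ti[i] <- j
    w1[i] <- wts[1]; w2[i] <- wts[2]; w3[i] <- wts[3]
  }
  list(t = tris[ti, , drop = FALSE], w1 = w1, w2 = w2, w3 = w3)
}
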