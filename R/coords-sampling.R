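# Grid conventions: 1-based array indices; the world position of element i
# along an axis is origin + (i - 1) * spacing (pixel-centre convention).
# Out-of-domain samples return the background value 0; tissue masks are
# strictly > 0 so background never masquerades as tissue.

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.worldToIndex <- function(w, origin, spacing) (w - origin) / spacing + 1

.indexToWorld <- function(i, origin, spacing) origin + (i - 1) * spacing

# Bilinear sampling of a matrix at fractional 1-based (ri, ci); outside the
# grid the background value fills in (partial weights near the border).
.bilinear2 <- function(mat, ri, ci, background = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- rep(background, length(r))
    if (any(ok)) out[ok] <- mat[cbind(r[ok], c[ok])]
    out
  }
  get(r0, c0) * (1 - fr) * (1 - fc) +
    get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc +
    get(r0 + 1, c0 + 1) * fr * fc
}

.nearest2 <- function(mat, ri, ci, background = 0) {
  r <- round(ri); c <- round(ci)
  nr <- nrow(mat); nc <- ncol(mat)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  out <- rep(background, length(ri))
  if (any(ok)) out[ok] <- mat[cbind(r[ok], c[ok])]
  out
}

.trilinear3 <- function(arr, xi, yi, zi, background = 0) {
  d <- dim(arr)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  get <- function(x, y, z) {
    ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
    out <- rep(background, length(x))
    if (any(ok)) out[ok] <- arr[cbind(x[ok], y[ok], z[ok])]
    out
  }
  get(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    get(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    get(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    get(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    get(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    get(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    get(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    get(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
}

.nearest3 <- function(arr, xi, yi, zi, background = 0) {
  d <- dim(arr)
  x <- round(xi); y <- round(yi); z <- round(zi)
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(background, length(xi))
  if (any(ok)) out[ok] <- arr[cbind(x[ok], y[ok], z[ok])]
  out
}

#' Sample an image or volume at world coordinates
#'
#' Interpolates pixel/voxel values at arbitrary world positions (mm).
#' Positions outside the grid return the background value 0.
#'
#' @param x an [Image2D] or [Volume3D] (masks included).
#' @param pts n x 2 (image) or n x 3 (volume) matrix of world coordinates
#'   in mm.
#' @param mode "linear" or "nearest".
#' @return numeric vector of sampled values.
#' @export
sampleAt <- function(x, pts, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  pts <- as.matrix(pts)
  if (is(x, "Image2D")) {
    ri <- .worldToIndex(pts[, 1], x@origin[1], x@spacing[1])
    ci <- .worldToIndex(pts[, 2], x@origin[2], x@spacing[2])
    if (mode == "linear") .bilinear2(x@values, ri, ci)
    else .nearest2(x@values, ri, ci)
  } else if (is(x, "Volume3D")) {
    xi <- .worldToIndex(pts[, 1], x@origin[1], x@spacing[1])
    yi <- .worldToIndex(pts[, 2], x@origin[2], x@spacing[2])
    zi <- .worldToIndex(pts[, 3], x@origin[3], x@spacing[3])
    if (mode == "linear") .trilinear3(x@values, xi, yi, zi)
    else .nearest3(x@values, xi, yi, zi)
  } else stop("sampleAt: unsupported object")
}

# ---- separable Gaussian smoothing --------------------------------------

.gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift an array along one axis, replicating the edge slab.
.shiftAxis <- function(a, axis, by) {
  if (by == 0) return(a)
  d <- dim(a); n <- d[axis]
  idx <- pmin(pmax(seq_len(n) - by, 1L), n)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# Separable Gaussian blur of a 2D or 3D array, sigma in grid units
# (per-axis if a vector). Edge handling: replicate.
.gaussSmooth <- function(a, sigma) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  sigma <- rep(sigma, length.out = length(d))
  out <- a
  for (ax in seq_along(d)) {
    if (sigma[ax] <= 0 || d[ax] == 1) next
    k <- .gaussKernel1d(sigma[ax])
    r <- (length(k) - 1L) / 2L
    acc <- array(0, d)
    for (j in seq_along(k))
      acc <- acc + k[j] * .shiftAxis(out, ax, j - 1L - r)
    out <- acc
  }
  out
}

# ---- resampling ---------------------------------------------------------

# Output grid preserving the world bounding box of the input grid: the
# half-voxel borders line up, so an exact factor-2 downsample places each
# output centre at the midpoint of a 2x2(x2) block of input centres.
.resampledAxis <- function(n, origin, spacing, res) {
  lo <- origin - spacing / 2
  extent <- n * spacing
  nOut <- max(1L, as.integer(round(extent / res)))
  list(n = nOut, origin = lo + res / 2)
}

#' Resample a volume onto an isotropic grid
#'
#' The output grid covers the same world bounding box at `resMm` isotropic
#' spacing. Linear mode preserves the value of a constant volume exactly.
#'
#' @param v a [Volume3D] (or [GMMask3D]).
#' @param resMm target isotropic voxel size (mm), > 0.
#' @param mode "linear" or "nearest".
#' @return a resampled object of the same class.
#' @export
resampleVolume <- function(v, resMm, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(resMm > 0)
  d <- dim(v@values)
  ax <- lapply(1:3, function(i)
    .resampledAxis(d[i], v@origin[i], v@spacing[i], resMm))
  nOut <- vapply(ax, `[[`, integer(1), "n")
  orig <- vapply(ax, `[[`, numeric(1), "origin")
  g <- expand.grid(x = seq_len(nOut[1]), y = seq_len(nOut[2]),
                   z = seq_len(nOut[3]))
  w <- cbind(.indexToWorld(g$x, orig[1], resMm),
             .indexToWorld(g$y, orig[2], resMm),
             .indexToWorld(g$z, orig[3], resMm))
  xi <- .worldToIndex(w[, 1], v@origin[1], v@spacing[1])
  yi <- .worldToIndex(w[, 2], v@origin[2], v@spacing[2])
  zi <- .worldToIndex(w[, 3], v@origin[3], v@spacing[3])
  vals <- if (mode == "linear") .trilinear3(v@values, xi, yi, zi)
          else .nearest3(v@values, xi, yi, zi)
  arr <- array(vals, nOut)
  if (is(v, "GMMask3D")) {
    arr <- pmin(pmax(arr, 0), 1)
    GMMask3D(arr, spacing = rep(resMm, 3), origin = orig,
             cutAxis = v@cutAxis,
             isBinary = mode == "nearest" && v@isBinary)
  } else {
    Volume3D(arr, spacing = rep(resMm, 3), origin = orig,
             cutAxis = v@cutAxis)
  }
}

#' Resample a 2D image onto an isotropic in-plane grid
#'
#' @param img an [Image2D] (or [GMMask2D]).
#' @param resMm target pixel size (mm), > 0.
#' @param mode "linear" or "nearest".
#' @return a resampled object of the same class.
#' @export
resampleImage2D <- function(img, resMm, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(resMm > 0)
  d <- dim(img@values)
  ax <- lapply(1:2, function(i)
    .resampledAxis(d[i], img@origin[i], img@spacing[i], resMm))
  nOut <- vapply(ax, `[[`, integer(1), "n")
  orig <- vapply(ax, `[[`, numeric(1), "origin")
  g <- expand.grid(r = seq_len(nOut[1]), c = seq_len(nOut[2]))
  ri <- .worldToIndex(.indexToWorld(g$r, orig[1], resMm),
                      img@origin[1], img@spacing[1])
  ci <- .worldToIndex(.indexToWorld(g$c, orig[2], resMm),
                      img@origin[2], img@spacing[2])
  vals <- if (mode == "linear") .bilinear2(img@values, ri, ci)
          else .nearest2(img@values, ri, ci)
  m <- matrix(vals, nOut[1], nOut[2])
  if (is(img, "GMMask2D")) {
    m <- pmin(pmax(m, 0), 1)
    GMMask2D(m, spacing = rep(resMm, 2), origin = orig,
             isBinary = mode == "nearest" && img@isBinary)
  } else {
    Image2D(m, spacing = rep(resMm, 2), origin = orig)
  }
}

#' Extract one cutting-axis plane of a volume as an image
#'
#' @param v a [Volume3D] or [GMMask3D].
#' @param j 1-based plane index along the cutting axis.
#' @return an [Image2D] (or [GMMask2D] for masks) carrying the in-plane
#'   grid metadata of the volume.
#' @export
extractPlane <- function(v, j) {
  ax <- v@cutAxis
  d <- dim(v@values)
  stopifnot(j >= 1, j <= d[ax])
  keep <- setdiff(1:3, ax)
  m <- switch(ax,
              v@values[j, , ],
              v@values[, j, ],
              v@values[, , j])
  sp <- v@spacing[keep]; org <- v@origin[keep]
  if (is(v, "GMMask3D")) GMMask2D(m, spacing = sp, origin = org,
                                  isBinary = v@isBinary)
  else Image2D(m, spacing = sp, origin = org)
}

#' World coordinate of a plane along the cutting axis
#' @param v a [Volume3D].
#' @param j plane index (may be fractional).
#' @return world coordinate in mm.
#' @export
planeWorld <- function(v, j) .indexToWorld(j, v@origin[v@cutAxis],
                                           v@spacing[v@cutAxis])
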