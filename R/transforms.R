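# Transform machinery. Every stored transform is usable in pull-back form:
# resampling an image onto a target grid samples the source at the pulled-
# back position of each target pixel. This keeps chain application a single
# resampling pass regardless of chain length.

.deg2rad <- function(d) d * pi / 180

#' Forward-map points through a rigid transform
#' @param t a [Rigid2D].
#' @param pts n x 2 matrix of world points (mm).
#' @return n x 2 matrix of mapped points.
#' @export
rigidForward <- function(t, pts) {
  a <- .deg2rad(t@thetaDeg)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(pts, 2, t@center) %*% t(R), 2,
        t@center + t@translation, `+`)
}

#' Pull points back through a rigid transform (inverse map)
#' @inheritParams rigidForward
#' @return n x 2 matrix of source-space points.
#' @export
rigidPullback <- function(t, pts) {
  a <- .deg2rad(-t@thetaDeg)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(pts, 2, t@center + t@translation) %*% t(R), 2, t@center, `+`)
}

#' Invert a rigid transform
#' @param t a [Rigid2D].
#' @return the inverse [Rigid2D] (same centre).
#' @export
invertRigid2D <- function(t) {
  a <- .deg2rad(-t@thetaDeg)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Rigid2D(thetaDeg = -t@thetaDeg,
          translation = as.numeric(-R %*% t@translation),
          center = t@center)
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param second,first [Rigid2D] objects.
#' @return the composed [Rigid2D], centred at `first`'s centre.
#' @export
composeRigid2D <- function(second, first) {
  c0 <- first@center
  img <- rigidForward(second, rigidForward(first, matrix(c0, 1)))
  Rigid2D(thetaDeg = first@thetaDeg + second@thetaDeg,
          translation = as.numeric(img) - c0,
          center = c0)
}

# Sample a displacement field (per-component linear interpolation) at world
# points; zero displacement outside the field grid.
.fieldAt2 <- function(f, pts) {
  ri <- .worldToIndex(pts[, 1], f@origin[1], f@spacing[1])
  ci <- .worldToIndex(pts[, 2], f@origin[2], f@spacing[2])
  cbind(.bilinear2(f@u[[1]], ri, ci), .bilinear2(f@u[[2]], ri, ci))
}

.fieldAt3 <- function(f, pts) {
  xi <- .worldToIndex(pts[, 1], f@origin[1], f@spacing[1])
  yi <- .worldToIndex(pts[, 2], f@origin[2], f@spacing[2])
  zi <- .worldToIndex(pts[, 3], f@origin[3], f@spacing[3])
  cbind(.trilinear3(f@u[[1]], xi, yi, zi),
        .trilinear3(f@u[[2]], xi, yi, zi),
        .trilinear3(f@u[[3]], xi, yi, zi))
}

#' Pull points back through a whole transform chain
#'
#' The chain is applied to images in the fixed order rigid -> warps (schedule
#' order); the pull-back therefore visits the warps in reverse, then the
#' rigid: `src = R^-1( x + u_K(x) + ... )` evaluated sequentially.
#'
#' @param chain a [TransformChain].
#' @param pts n x 2 matrix of target-space world points (mm).
#' @param nWarps number of leading warps to include (default all).
#' @return n x 2 matrix of source-space points.
#' @export
chainPullback <- function(chain, pts, nWarps = length(chain@warps)) {
  p <- as.matrix(pts)
  if (nWarps > 0)
    for (k in rev(seq_len(nWarps)))
      p <- p + .fieldAt2(chain@warps[[k]], p)
  rigidPullback(chain@rigid, p)
}

#' Apply 2D transforms to an image by resampling onto a target grid
#'
#' @param img source [Image2D] / [GMMask2D].
#' @param transform a [Rigid2D], [Deformation2D] or [TransformChain].
#' @param outGrid target grid: an [Image2D]-like object to copy the grid
#'   from, or a list with `dim`, `spacing`, `origin`.
#' @param mode "linear" or "nearest"; out-of-domain pixels are background 0.
#' @return the resampled image on `outGrid`, same class as `img`.
#' @export
applyTransform2D <- function(img, transform, outGrid = img,
                             mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (is(outGrid, "Image2D"))
    outGrid <- list(dim = dim(outGrid@values), spacing = outGrid@spacing,
                    origin = outGrid@origin)
  if (is.null(outGrid$dim)) stop("applyTransform2D: undefined output grid")
  g <- expand.grid(r = seq_len(outGrid$dim[1]), c = seq_len(outGrid$dim[2]))
  pts <- cbind(.indexToWorld(g$r, outGrid$origin[1], outGrid$spacing[1]),
               .indexToWorld(g$c, outGrid$origin[2], outGrid$spacing[2]))
  src <- if (is(transform, "TransformChain")) chainPullback(transform, pts)
         else if (is(transform, "Rigid2D")) rigidPullback(transform, pts)
         else if (is(transform, "Deformation2D")) pts + .fieldAt2(transform, pts)
         else stop("applyTransform2D: unsupported transform")
  vals <- sampleAt(img, src, mode = mode)
  m <- matrix(vals, outGrid$dim[1], outGrid$dim[2])
  if (is(img, "GMMask2D"))
    GMMask2D(pmin(pmax(m, 0), 1), spacing = outGrid$spacing,
             origin = outGrid$origin,
             isBinary = mode == "nearest" && img@isBinary)
  else Image2D(m, spacing = outGrid$spacing, origin = outGrid$origin)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse of `phi(x) = x + u(x)`:
#' `v_{k+1}(y) = -u(y + v_k(y))`. Converges for the smooth, small-magnitude
#' fields produced by the deformable registration.
#'
#' @param f a [Deformation2D] or [Deformation3D].
#' @param iters number of fixed-point iterations.
#' @return a field of the same class on the same grid.
#' @export
invertDeformation <- function(f, iters = 20L) {
  nd <- length(f@u)
  d <- dim(as.array(f@u[[1]]))
  grids <- lapply(seq_len(nd), function(ax) {
    idx <- slice.index(array(0, d), ax)
    .indexToWorld(idx, f@origin[ax], f@spacing[ax])
  })
  pts <- do.call(cbind, lapply(grids, as.numeric))
  v <- matrix(0, nrow(pts), nd)
  at <- if (nd == 2) .fieldAt2 else .fieldAt3
  for (i in seq_len(iters)) v <- -at(f, pts + v)
  u <- lapply(seq_len(nd), function(ax) array(v[, ax], d))
  if (nd == 2) Deformation2D(u, f@spacing, f@origin)
  else Deformation3D(u, f@spacing, f@origin)
}

# ---- transform persistence ---------------------------------------------

#' Write / read a transform chain
#'
#' Rigid parameters go to a JSON sidecar; displacement fields are stored as
#' NIfTI vector images (one file per warp, components along the 4th axis).
#'
#' @param chain a [TransformChain].
#' @param prefix output path prefix (files `<prefix>.json`,
#'   `<prefix>_warp<k>.nii.gz`).
#' @return `readTransformChain` returns the reassembled [TransformChain];
#'   `writeTransformChain` returns `prefix` invisibly.
#' @export
writeTransformChain <- function(chain, prefix) {
  meta <- list(
    rigid = list(thetaDeg = chain@rigid@thetaDeg,
                 translation = chain@rigid@translation,
                 center = chain@rigid@center),
    warps = lapply(seq_along(chain@warps), function(k) {
      w <- chain@warps[[k]]
      file <- paste0(prefix, "_warp", k, ".nii.gz")
      arr <- array(0, c(dim(w@u[[1]]), 1, 2))
      arr[, , 1, 1] <- w@u[[1]]; arr[, , 1, 2] <- w@u[[2]]
      img <- RNifti::asNifti(arr, pixdim = c(w@spacing, 1, 1))
      RNifti::writeNifti(img, file)
      list(file = basename(file), spacing = w@spacing, origin = w@origin)
    }))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeTransformChain
#' @export
readTransformChain <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = FALSE)
  rigid <- Rigid2D(thetaDeg = meta$rigid$thetaDeg,
                   translation = unlist(meta$rigid$translation),
                   center = unlist(meta$rigid$center))
  warps <- lapply(meta$warps, function(w) {
    img <- RNifti::readNifti(file.path(dirname(prefix), w$file))
    arr <- array(as.numeric(img), dim(img))
    Deformation2D(list(arr[, , 1, 1], arr[, , 1, 2]),
                  spacing = unlist(w$spacing), origin = unlist(w$origin))
  })
  TransformChain(rigid = rigid, warps = warps)
}
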