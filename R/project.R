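# Stage 3 plumbing: sampling acquired sections onto depth-surface vertices
# in slab space, and projecting completed per-vertex fields back into a
# volume over the cortical ribbon.

#' Sample acquired sections onto depth-surface vertices
#'
#' For every vertex of every depth surface (already transformed into the
#' native/slab coordinate space), the nearest acquired section plane of the
#' requested acquisition within half a section thickness captures the
#' vertex; its value is the nearest-neighbour pixel of the raw section
#' sampled through the full inverse transform chain (so the value comes
#' from the aligned position). All other vertices are missing.
#'
#' @param stack a [SectionStack] (one slab).
#' @param chains named list of [TransformChain]s by image ref.
#' @param depthSet a [DepthSurfaceSet] in slab space.
#' @param images named list of raw section [Image2D]s by image ref.
#' @param acquisition acquisition label to sample.
#' @param mode pixel interpolation ("nearest" per the sampling contract).
#' @param gmMasks optional named list of section GM masks; when given, a
#'   vertex is only accepted if its sampled pixel lies inside the
#'   section's GM (pixels off the tissue carry no signal for the
#'   acquisition and would contaminate the border surfaces).
#' @return list of [VertexField]s, one per depth surface; attribute
#'   `"warning"` set when the acquisition has no acquired sections.
#' @export
sampleSectionsToVertices <- function(stack, chains, depthSet, images,
                                     acquisition, mode = "nearest",
                                     gmMasks = NULL) {
  rec <- stack@records[stack@records$qc_pass &
                       stack@records$acquisition == acquisition, ,
                       drop = FALSE]
  nV <- nrow(depthSet@meshes[[1]]@vertices)
  if (nrow(rec) == 0) {
    out <- lapply(depthSet@meshes, function(m)
      VertexField(rep(NA_real_, nV), rep(FALSE, nV)))
    attr(out, "warning") <- "no acquired sections for this acquisition"
    warning("sampleSectionsToVertices: no acquired sections for ",
            acquisition)
    return(out)
  }
  thick <- rec$section_thickness_um[1] / 1000
  planeY <- rec$sample * thick
  ord <- order(planeY)
  rec <- rec[ord, , drop = FALSE]; planeY <- planeY[ord]

  lapply(depthSet@meshes, function(mesh) {
    v <- mesh@vertices
    # nearest acquired plane per vertex
    pos <- findInterval(v[, 2], planeY)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(planeY))
    dLo <- abs(v[, 2] - planeY[lo]); dHi <- abs(v[, 2] - planeY[hi])
    near <- ifelse(dHi < dLo, hi, lo)
    dist <- pmin(dLo, dHi)
    captured <- dist <= thick / 2
    vals <- rep(NA_real_, nV)
    inGM <- rep(TRUE, nV)
    for (si in unique(near[captured])) {
      sel <- which(captured & near == si)
      key <- rec$image[si]
      ch <- chains[[key]] %||% TransformChain()
      src <- chainPullback(ch, v[sel, c(1, 3), drop = FALSE])
      vals[sel] <- sampleAt(images[[key]], src, mode = mode)
      if (!is.null(gmMasks))
        inGM[sel] <- sampleAt(gmMasks[[key]], src, mode = "nearest") > 0.5
    }
    VertexField(vals, captured & is.finite(vals) & inGM)
  })
}

#' Project per-depth vertex fields into a volume
#'
#' Every cortical voxel takes the mean of all depth-surface vertex values
#' falling inside it; cortical voxels containing no vertex are filled by
#' iterative neighbour averaging restricted to the cortex mask (Laplacian
#' fill, which reduces to linear interpolation across 1D gaps). Non-cortex
#' voxels are background 0.
#'
#' @param depthFields list of complete [VertexField]s (one per depth
#'   surface).
#' @param depthSet the [DepthSurfaceSet] in the output coordinate space.
#' @param outGrid a [Volume3D]-like grid template, or list
#'   dim/spacing/origin.
#' @param cortexMask binary [GMMask3D] on `outGrid` marking the cortical
#'   ribbon.
#' @param fill run the gap fill (TRUE) or leave uncovered voxels at 0.
#' @return a [Volume3D]; attribute `"coverage"` gives the fraction of
#'   cortical voxels containing at least one vertex before gap filling.
#' @export
projectToVolume <- function(depthFields, depthSet, outGrid, cortexMask,
                            fill = TRUE) {
  if (is(outGrid, "Volume3D"))
    outGrid <- list(dim = dim(outGrid@values), spacing = outGrid@spacing,
                    origin = outGrid@origin)
  d <- outGrid$dim
  acc <- array(0, d); cnt <- array(0, d)
  for (k in seq_along(depthFields)) {
    v <- depthSet@meshes[[k]]@vertices
    f <- depthFields[[k]]@values
    ok <- depthFields[[k]]@known & is.finite(f)
    if (!any(ok)) next
    ix <- round(.worldToIndex(v[ok, 1], outGrid$origin[1], outGrid$spacing[1]))
    iy <- round(.worldToIndex(v[ok, 2], outGrid$origin[2], outGrid$spacing[2]))
    iz <- round(.worldToIndex(v[ok, 3], outGrid$origin[3], outGrid$spacing[3]))
    keep <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    if (!any(keep)) next
    lin <- cbind(ix[keep], iy[keep], iz[keep])
    vals <- f[ok][keep]
    li <- (lin[, 3] - 1L) * d[1] * d[2] + (lin[, 2] - 1L) * d[1] + lin[, 1]
    sums <- rowsum(vals, li)
    counts <- rowsum(rep(1, length(li)), li)
    at <- as.integer(rownames(sums))
    acc[at] <- acc[at] + sums[, 1]
    cnt[at] <- cnt[at] + counts[, 1]
  }
  cortex <- cortexMask@values > 0.5
  if (!any(cnt[cortex] > 0))
    stop("projectToVolume: no vertices fall inside the cortex mask")
  out <- array(0, d)
  covered <- cnt > 0
  out[covered] <- acc[covered] / cnt[covered]
  coverage <- sum(covered & cortex) / sum(cortex)
  if (fill) out <- .laplacianFill(out, covered & cortex, cortex)
  out[!cortex] <- 0
  vol <- Volume3D(out, spacing = outGrid$spacing, origin = outGrid$origin)
  attr(vol, "coverage") <- coverage
  vol
}

# Fill unknown voxels inside `domain` from known neighbours: first an
# outward sweep seeds every unknown voxel from the mean of its already-
# valued 6-neighbours, then Jacobi relaxation of the filled voxels until
# convergence (Dirichlet data = originally known voxels).
.laplacianFill <- function(vals, known, domain, tol = 1e-4,
                           maxSweep = 200L, maxRelax = 100L) {
  neighSum <- function(v, m) {
    s <- array(0, dim(v)); c <- array(0, dim(v))
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      s <- s + .shiftAxis(v * m, ax, by)
      c <- c + .shiftAxis(m * 1, ax, by)
    }
    list(s = s, c = c)
  }
  filled <- known
  for (i in seq_len(maxSweep)) {
    todo <- domain & !filled
    if (!any(todo)) break
    ns <- neighSum(vals, filled)
    new <- todo & ns$c > 0
    if (!any(new)) break
    vals[new] <- ns$s[new] / ns$c[new]
    filled <- filled | new
  }
  free <- domain & !known & filled
  if (any(free)) {
    for (i in seq_len(maxRelax)) {
      ns <- neighSum(vals, filled)
      upd <- free & ns$c > 0
      nv <- ns$s[upd] / ns$c[upd]
      delta <- max(abs(nv - vals[upd]), 0)
      vals[upd] <- nv
      if (delta < tol * max(abs(vals[known]), 1)) break
    }
  }
  vals
}

#' Map reference-space depth surfaces into slab space
#'
#' Applies the inverse of the 3D registration pull-back (which maps
#' reconstruction points to reference points) to every vertex, carrying
#' the whole depth set into the slab's reconstruction space.
#'
#' @param depthSet [DepthSurfaceSet] in reference space.
#' @param registration the [register3D()] result for the slab.
#' @return the transformed [DepthSurfaceSet] (spaceTag "slab").
#' @export
depthSurfacesToSlab <- function(depthSet, registration) {
  meshes <- lapply(depthSet@meshes, function(m) {
    v <- invertPullback(registration$pullback, m@vertices)
    SurfaceMesh(v, m@triangles, spaceTag = "slab")
  })
  DepthSurfaceSet(meshes, depthSet@depths)
}
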