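#' @import methods
NULL

# ---- grid-carrying raster containers -----------------------------------

#' Image2D: a 2D section image with grid metadata
#'
#' A plain real-valued matrix plus the in-plane world geometry needed to
#' place it: per-axis pixel spacing (mm) and the world offset of the centre
#' of pixel (1,1). Rows map to the first in-plane world axis, columns to the
#' second. All coordinates use the pixel-centre convention: the world
#' position of pixel (i, j) is `origin + (c(i, j) - 1) * spacing`.
#'
#' @slot values numeric matrix of pixel values (finite).
#' @slot spacing numeric(2), pixel spacing in mm (row, col), both > 0.
#' @slot origin numeric(2), world coordinate (mm) of the centre of pixel
#'   (1,1).
#' @export
setClass("Image2D",
  representation(values = "matrix", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1), origin = c(0, 0))
)

setValidity("Image2D", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    return("spacing must be two positive reals (mm)")
  if (length(object@origin) != 2) return("origin must have length 2")
  TRUE
})

#' Construct an Image2D
#'
#' @param values numeric matrix.
#' @param spacing numeric(2) pixel spacing in mm.
#' @param origin numeric(2) world position (mm) of pixel (1,1) centre.
#' @return an [Image2D] object.
#' @export
Image2D <- function(values, spacing = c(1, 1), origin = c(0, 0)) {
  new("Image2D", values = as.matrix(values), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Volume3D: a 3D volume with grid metadata
#'
#' Array axes are (x, y, z) in a right-handed world frame; the cutting
#' (coronal) axis is array axis 2 by default. World units are mm,
#' voxel-centre convention as for [Image2D].
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) world coordinate of voxel (1,1,1) centre.
#' @slot cutAxis integer, which array axis is the cutting axis (default 2).
#' @export
setClass("Volume3D",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 cutAxis = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), cutAxis = 2L)
)

setValidity("Volume3D", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("values must be finite")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be three positive reals (mm)")
  if (length(object@origin) != 3) return("origin must have length 3")
  if (!object@cutAxis %in% 1:3) return("cutAxis must be 1, 2 or 3")
  TRUE
})

#' Construct a Volume3D
#' @param values 3D numeric array.
#' @param spacing numeric(3) voxel spacing (mm).
#' @param origin numeric(3) world position (mm) of voxel (1,1,1) centre.
#' @param cutAxis integer cutting-axis index (default 2, coronal).
#' @return a [Volume3D].
#' @export
Volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     cutAxis = 2L) {
  new("Volume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), cutAxis = as.integer(cutAxis))
}

#' Gray-matter masks
#'
#' `GMMask2D` / `GMMask3D` carry a segmentation in \[0,1\] on the same grid
#' conventions as [Image2D] / [Volume3D]. When `isBinary` is TRUE all values
#' are exactly 0 or 1; fuzzy masks (e.g. gap-interpolated planes) keep
#' fractional values.
#'
#' @slot isBinary logical flag.
#' @rdname GMMask
#' @export
setClass("GMMask2D", contains = "Image2D",
         representation(isBinary = "logical"), prototype(isBinary = TRUE))

#' @rdname GMMask
#' @export
setClass("GMMask3D", contains = "Volume3D",
         representation(isBinary = "logical"), prototype(isBinary = TRUE))

.checkMaskValues <- function(v, isBinary) {
  if (min(v) < 0 || max(v) > 1) return("mask values must lie in [0,1]")
  if (isBinary && !all(v %in% c(0, 1)))
    return("binary mask values must be exactly 0 or 1")
  TRUE
}
setValidity("GMMask2D", function(object)
  .checkMaskValues(object@values, object@isBinary))
setValidity("GMMask3D", function(object)
  .checkMaskValues(object@values, object@isBinary))

#' Construct gray-matter masks
#' @param values matrix (2D) or array (3D) in \[0,1\].
#' @param spacing,origin grid metadata, as for [Image2D]/[Volume3D].
#' @param isBinary logical; TRUE when values are strictly 0/1.
#' @param cutAxis cutting-axis index for the 3D mask.
#' @return a `GMMask2D` or `GMMask3D`.
#' @rdname GMMask
#' @export
GMMask2D <- function(values, spacing = c(1, 1), origin = c(0, 0),
                     isBinary = all(values %in% c(0, 1))) {
  new("GMMask2D", values = as.matrix(values), spacing = as.numeric(spacing),
      origin = as.numeric(origin), isBinary = isBinary)
}

#' @rdname GMMask
#' @export
GMMask3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     cutAxis = 2L, isBinary = all(values %in% c(0, 1))) {
  new("GMMask3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), cutAxis = as.integer(cutAxis),
      isBinary = isBinary)
}

# ---- transforms ---------------------------------------------------------

#' Rigid2D: an in-plane rigid transform
#'
#' Parameterised by a rotation (degrees, counter-clockwise in (row, col)
#' world coordinates), a translation (mm) and a rotation centre (mm). The
#' forward map sends moving-space points to fixed-space points:
#' `p' = R(theta) (p - centre) + centre + t`.
#'
#' @slot thetaDeg rotation angle in degrees.
#' @slot translation numeric(2) translation (mm).
#' @slot center numeric(2) rotation centre (mm).
#' @export
setClass("Rigid2D",
  representation(thetaDeg = "numeric", translation = "numeric",
                 center = "numeric"),
  prototype(thetaDeg = 0, translation = c(0, 0), center = c(0, 0))
)

setValidity("Rigid2D", function(object) {
  if (length(object@thetaDeg) != 1 || !is.finite(object@thetaDeg))
    return("thetaDeg must be a finite scalar")
  if (length(object@translation) != 2 || any(!is.finite(object@translation)))
    return("translation must be finite length-2")
  if (length(object@center) != 2) return("center must have length 2")
  TRUE
})

#' @param thetaDeg,translation,center see slots.
#' @return a `Rigid2D`.
#' @rdname Rigid2D-class
#' @export
Rigid2D <- function(thetaDeg = 0, translation = c(0, 0), center = c(0, 0)) {
  new("Rigid2D", thetaDeg = thetaDeg, translation = as.numeric(translation),
      center = as.numeric(center))
}

#' Dense displacement fields
#'
#' `Deformation2D` / `Deformation3D` store pull-back displacement fields in
#' mm on a stated grid: resampling an image through the field samples the
#' source at `x + u(x)` for each target-grid point `x`. An identity field
#' (all zeros) reproduces the input up to resampling.
#'
#' @slot u list of per-axis displacement arrays (mm), all the same shape.
#' @slot spacing grid spacing (mm).
#' @slot origin world position of the first grid node (mm).
#' @rdname Deformation
#' @export
setClass("Deformation2D",
  representation(u = "list", spacing = "numeric", origin = "numeric"))

#' @rdname Deformation
#' @export
setClass("Deformation3D",
  representation(u = "list", spacing = "numeric", origin = "numeric"))

.checkField <- function(object, nd) {
  if (length(object@u) != nd) return(sprintf("u must hold %d arrays", nd))
  d <- dim(as.array(object@u[[1]]))
  for (comp in object@u) {
    if (anyNA(comp) || any(!is.finite(comp))) return("field must be finite")
    if (!identical(dim(as.array(comp)), d)) return("field components differ in shape")
  }
  if (length(object@spacing) != nd || any(object@spacing <= 0))
    return("spacing must be positive")
  TRUE
}
setValidity("Deformation2D", function(object) .checkField(object, 2L))
setValidity("Deformation3D", function(object) .checkField(object, 3L))

#' @param u list of displacement arrays (mm).
#' @param spacing,origin field grid metadata (mm).
#' @return a `Deformation2D` / `Deformation3D`.
#' @rdname Deformation
#' @export
Deformation2D <- function(u, spacing = c(1, 1), origin = c(0, 0)) {
  new("Deformation2D", u = u, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname Deformation
#' @export
Deformation3D <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Deformation3D", u = u, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' TransformChain: the per-section transform stack
#'
#' Application order is fixed: the stage-1 rigid first, then the per-
#' resolution 2D deformations in schedule order. Each element is stored in
#' pull-back form so the chain can be applied to a section image in one
#' resampling pass.
#'
#' @slot rigid the initial [Rigid2D].
#' @slot warps list of [Deformation2D], one per completed refinement pass,
#'   in schedule order.
#' @export
setClass("TransformChain",
  representation(rigid = "Rigid2D", warps = "list"),
  prototype(warps = list())
)

setValidity("TransformChain", function(object) {
  for (w in object@warps)
    if (!is(w, "Deformation2D")) return("warps must be Deformation2D objects")
  TRUE
})

#' @param rigid initial [Rigid2D].
#' @param warps list of [Deformation2D] refinements (schedule order).
#' @return a `TransformChain`.
#' @rdname TransformChain-class
#' @export
TransformChain <- function(rigid = Rigid2D(), warps = list()) {
  new("TransformChain", rigid = rigid, warps = warps)
}

# ---- meshes and vertex data --------------------------------------------

#' SurfaceMesh: a triangulated cortical surface
#'
#' @slot vertices n x 3 matrix of vertex coordinates (mm, or unit vectors in
#'   sphere space).
#' @slot triangles m x 3 integer matrix of 1-based vertex indices.
#' @slot spaceTag one of "reference", "slab", "sphere".
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 spaceTag = "character"),
  prototype(spaceTag = "reference")
)

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; tr <- object@triangles
  if (ncol(v) != 3) return("vertices must be n x 3")
  if (ncol(tr) != 3) return("triangles must be m x 3")
  if (nrow(tr) > 0) {
    if (min(tr) < 1 || max(tr) > nrow(v)) return("triangle index out of range")
    a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]
    cc <- v[tr[, 3], , drop = FALSE]
    n <- .rowCross(b - a, cc - a)
    if (any(sqrt(rowSums(n^2)) <= 0)) return("degenerate (zero-area) triangle")
  }
  if (!object@spaceTag %in% c("reference", "slab", "sphere"))
    return("spaceTag must be reference|slab|sphere")
  if (object@spaceTag == "sphere" &&
      any(abs(sqrt(rowSums(v^2)) - 1) > 1e-6))
    return("sphere-space vertices must be unit norm")
  TRUE
})

#' @param vertices n x 3 coordinate matrix.
#' @param triangles m x 3 integer index matrix (1-based).
#' @param spaceTag coordinate space label.
#' @return a `SurfaceMesh`.
#' @rdname SurfaceMesh-class
#' @export
SurfaceMesh <- function(vertices, triangles, spaceTag = "reference") {
  storage.mode(triangles) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices), triangles = triangles,
      spaceTag = spaceTag)
}

#' DepthSurfaceSet: shared-topology meshes spanning the cortical depth
#'
#' Mesh `i` sits at fractional depth `depths[i]`, with depth 0 the WM-GM
#' border and depth 1 the pial surface; every vertex of mesh `i` lies on the
#' segment joining the corresponding WM and pial vertices.
#'
#' @slot meshes list of [SurfaceMesh], WM first, pial last.
#' @slot depths numeric vector of fractional depths in \[0,1\], increasing.
#' @export
setClass("DepthSurfaceSet",
  representation(meshes = "list", depths = "numeric"))

setValidity("DepthSurfaceSet", function(object) {
  if (length(object@meshes) != length(object@depths))
    return("one depth per mesh required")
  if (length(object@meshes) < 2) return("need at least WM and pial meshes")
  if (is.unsorted(object@depths)) return("depths must increase")
  tr <- object@meshes[[1]]@triangles
  for (m in object@meshes) {
    if (!is(m, "SurfaceMesh")) return("meshes must be SurfaceMesh objects")
    if (!identical(m@triangles, tr)) return("meshes must share one triangulation")
  }
  TRUE
})

#' @param meshes list of [SurfaceMesh] (WM first, pial last).
#' @param depths fractional depths in \[0,1\].
#' @return a `DepthSurfaceSet`.
#' @rdname DepthSurfaceSet-class
#' @export
DepthSurfaceSet <- function(meshes, depths) {
  new("DepthSurfaceSet", meshes = meshes, depths = as.numeric(depths))
}

#' VertexField: per-vertex values with an explicit missing mask
#'
#' @slot values numeric vector, one entry per mesh vertex (finite where
#'   known).
#' @slot known logical vector; TRUE where the value was measured.
#' @export
setClass("VertexField",
  representation(values = "numeric", known = "logical"))

setValidity("VertexField", function(object) {
  if (length(object@values) != length(object@known))
    return("values and known must have equal length")
  if (any(object@known & !is.finite(object@values)))
    return("known values must be finite")
  TRUE
})

#' @param values numeric per-vertex values.
#' @param known logical per-vertex measured flag.
#' @return a `VertexField`.
#' @rdname VertexField-class
#' @export
VertexField <- function(values, known = is.finite(values)) {
  new("VertexField", values = as.numeric(values), known = as.logical(known))
}

# ---- section bookkeeping ------------------------------------------------

#' SectionStack: the ordered manifest of 2D sections
#'
#' Wraps a data.frame with one row per section: `slab` (integer >= 1),
#' `sample` (integer >= 0, position along the cutting axis in section-
#' thickness units), `acquisition` (label, e.g. ligand or stain name),
#' `image` (path), `pixel_size_um`, `section_thickness_um`, `qc_pass`,
#' `exclude_reason`.
#'
#' @slot records data.frame as above, sorted by (slab, sample).
#' @slot axis cutting-axis name (default "coronal").
#' @slot speciesTag free-form species label.
#' @export
setClass("SectionStack",
  representation(records = "data.frame", axis = "character",
                 speciesTag = "character"),
  prototype(axis = "coronal", speciesTag = "phantom")
)

setValidity("SectionStack", function(object) {
  r <- object@records
  need <- c("slab", "sample", "acquisition", "image", "pixel_size_um",
            "section_thickness_um", "qc_pass", "exclude_reason")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("missing record columns:",
                                 paste(miss, collapse = ", ")))
  if (nrow(r) == 0) return("stack must be non-empty")
  if (any(r$slab < 1)) return("slab ids must be >= 1")
  if (any(r$sample < 0)) return("sample indices must be >= 0")
  if (anyDuplicated(r[, c("slab", "sample")]))
    return("(slab, sample) pairs must be unique")
  if (any(r$pixel_size_um <= 0)) return("pixel_size_um must be positive")
  th <- tapply(r$section_thickness_um, r$slab,
               function(x) length(unique(x)))
  if (any(th != 1)) return("section thickness must be constant within a slab")
  TRUE
})

#' @param records data.frame of section records.
#' @param axis cutting-axis name.
#' @param speciesTag species label.
#' @return a `SectionStack`.
#' @rdname SectionStack-class
#' @export
SectionStack <- function(records, axis = "coronal", speciesTag = "phantom") {
  if (is.null(records$qc_pass)) records$qc_pass <- TRUE
  if (is.null(records$exclude_reason)) records$exclude_reason <- NA_character_
  records <- records[order(records$slab, records$sample), , drop = FALSE]
  rownames(records) <- NULL
  new("SectionStack", records = records, axis = axis, speciesTag = speciesTag)
}

# ---- phantom ------------------------------------------------------------

#' Phantom: a synthetic ground-truth brain
#'
#' Holds the labelled truth volume (0 background, 1 WM, 2 cortical GM),
#' shared-topology WM/pial meshes, the analytic density-field parameters for
#' each acquisition, and the per-section perturbations applied when slicing.
#'
#' @slot truthVolume labelled [Volume3D].
#' @slot wmMesh,pialMesh shared-topology [SurfaceMesh]es.
#' @slot center numeric(3), world centre of the radial shape (mm).
#' @slot shape list of radial-shape parameters.
#' @slot fieldSpecs named list (per acquisition) of density-field wave
#'   parameters plus the intensity model (gain/offset/polarity/noise sd).
#' @slot seed integer seed the phantom was built with.
#' @export
setClass("Phantom",
  representation(truthVolume = "Volume3D", wmMesh = "SurfaceMesh",
                 pialMesh = "SurfaceMesh", center = "numeric",
                 shape = "list", fieldSpecs = "list", seed = "integer"))

# ---- show methods -------------------------------------------------------

setMethod("show", "Image2D", function(object) {
  cat(sprintf("%s %d x %d, spacing %.3g x %.3g mm\n", class(object),
              nrow(object@values), ncol(object@values),
              object@spacing[1], object@spacing[2]))
})

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %d x %d x %d, spacing %.3g/%.3g/%.3g mm, cut axis %d\n",
              class(object), d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3], object@cutAxis))
})

setMethod("show", "Rigid2D", function(object) {
  cat(sprintf("Rigid2D: theta %.3f deg, t (%.3f, %.3f) mm\n",
              object@thetaDeg, object@translation[1], object@translation[2]))
})

setMethod("show", "TransformChain", function(object) {
  cat(sprintf("TransformChain: rigid (theta %.2f deg) + %d warp(s)\n",
              object@rigid@thetaDeg, length(object@warps)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d triangles\n",
              object@spaceTag, nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "DepthSurfaceSet", function(object) {
  cat(sprintf("DepthSurfaceSet: %d surfaces, %d vertices each\n",
              length(object@meshes), nrow(object@meshes[[1]]@vertices)))
})

setMethod("show", "VertexField", function(object) {
  cat(sprintf("VertexField: %d vertices, %d known (%.1f%%)\n",
              length(object@values), sum(object@known),
              100 * mean(object@known)))
})

setMethod("show", "SectionStack", function(object) {
  r <- object@records
  cat(sprintf("SectionStack: %d sections, %d slab(s), %d acquisition(s) [%s]\n",
              nrow(r), length(unique(r$slab)),
              length(unique(r$acquisition)), object@axis))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@truthVolume@values)
  cat(sprintf("Phantom: truth %d x %d x %d, %d acquisition field(s), seed %d\n",
              d[1], d[2], d[3], length(object@fieldSpecs), object@seed))
})

# ---- accessors ----------------------------------------------------------

#' Grid and content accessors
#'
#' `values()` returns the raw array, `spacingMm()` the grid spacing,
#' `originMm()` the world position of the first pixel/voxel centre,
#' `records()` the manifest data.frame of a [SectionStack], `vertices()` and
#' `triangles()` the mesh arrays.
#'
#' @param x an object of one of the package classes.
#' @return the underlying array / metadata.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
#' @rdname accessors
#' @export
setMethod("pixelValues", "Image2D", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("pixelValues", "Volume3D", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
setMethod("spacingMm", "Image2D", function(x) x@spacing)
setMethod("spacingMm", "Volume3D", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))
setMethod("originMm", "Image2D", function(x) x@origin)
setMethod("originMm", "Volume3D", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
setMethod("records", "SectionStack", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)
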