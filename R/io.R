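# File-format surface: CSV manifests, PNG/TIFF/NIfTI sections, NIfTI
# volumes, Wavefront OBJ meshes.

#' Load a CSV section manifest
#'
#' Required columns: `slab`, `sample`, `acquisition`, `image`,
#' `pixel_size_um`. Optional: `section_thickness_um` (default 1000 um),
#' `qc_pass` (default TRUE), `exclude_reason`.
#'
#' @param path path to the CSV file.
#' @param axis cutting-axis name stored on the stack.
#' @param speciesTag species label stored on the stack.
#' @return a [SectionStack] sorted by (slab, sample).
#' @export
loadManifest <- function(path, axis = "coronal", speciesTag = "unknown") {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slab", "sample", "acquisition", "image", "pixel_size_um")
  for (col in need)
    if (!col %in% names(df))
      stop("manifest schema error: missing column '", col, "'")
  if (anyDuplicated(df[, c("slab", "sample")])) {
    d <- df[duplicated(df[, c("slab", "sample")]), c("slab", "sample")]
    stop("manifest integrity error: duplicate (slab, sample) = (",
         d$slab[1], ", ", d$sample[1], ")")
  }
  if (is.null(df$section_thickness_um)) df$section_thickness_um <- 1000
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  if (is.null(df$exclude_reason)) df$exclude_reason <- NA_character_
  df$exclude_reason <- as.character(df$exclude_reason)
  df$slab <- as.integer(df$slab)
  df$sample <- as.integer(df$sample)
  SectionStack(df, axis = axis, speciesTag = speciesTag)
}

#' Write a section manifest back to CSV
#' @param stack a [SectionStack].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(stack, path) {
  utils::write.csv(stack@records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a 2D section image
#'
#' PNG and TIFF pixels are rescaled to the 8-bit range \[0, 255\]
#' (16-bit sources are scaled down); 2D NIfTI values are taken as stored.
#'
#' @param path image path (.png, .tif/.tiff, .nii/.nii.gz).
#' @param pixelSizeUm in-plane pixel size in micrometres.
#' @param origin world position (mm) of pixel (1,1); default centres the
#'   image on (0,0).
#' @return an [Image2D].
#' @export
readSectionImage <- function(path, pixelSizeUm, origin = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  m <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 255
    },
    tif = ,
    tiff = {
      a <- tiff::readTIFF(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 255
    },
    nii = {
      a <- as.array(RNifti::readNifti(path))
      if (length(dim(a)) > 2) a <- a[, , 1]
      a
    },
    stop("unsupported section image format: ", path))
  sp <- rep(pixelSizeUm / 1000, 2)
  if (is.null(origin)) origin <- -(dim(m) - 1) / 2 * sp
  Image2D(m, spacing = sp, origin = origin)
}

#' Write a section image as 8-bit PNG
#' @param img an [Image2D] with values in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSectionImage <- function(img, path) {
  v <- pmin(pmax(img@values, 0), 255) / 255
  png::writePNG(v, path)
  invisible(path)
}

#' Read / write volumes as NIfTI-1
#'
#' The world origin is carried in the qoffset fields; axis order is kept as
#' stored (x, y, z).
#'
#' @param path NIfTI file path.
#' @param cutAxis cutting-axis index to tag the volume with.
#' @return `readVolumeNifti` returns a [Volume3D]; `writeVolumeNifti`
#'   returns `path` invisibly.
#' @export
readVolumeNifti <- function(path, cutAxis = 2L) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) > 3) arr <- arr[, , , 1]
  Volume3D(arr, spacing = hdr$pixdim[2:4],
           origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z),
           cutAxis = cutAxis)
}

#' @param v a [Volume3D] or [GMMask3D].
#' @rdname readVolumeNifti
#' @export
writeVolumeNifti <- function(v, path) {
  img <- RNifti::asNifti(v@values)
  RNifti::pixdim(img) <- v@spacing
  xf <- rbind(cbind(diag(v@spacing), v@origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write Wavefront OBJ meshes
#'
#' Only `v` and `f` records are used; faces must be triangles.
#'
#' @param path OBJ file path.
#' @param spaceTag coordinate-space tag for the mesh read in.
#' @return `readMeshObj` returns a [SurfaceMesh]; `writeMeshObj` returns
#'   `path` invisibly.
#' @export
readMeshObj <- function(path, spaceTag = "reference") {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  SurfaceMesh(v, f, spaceTag = spaceTag)
}

#' @param mesh a [SurfaceMesh].
#' @rdname readMeshObj
#' @export
writeMeshObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g", mesh@vertices[, 1],
                     mesh@vertices[, 2], mesh@vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh@triangles[, 1],
                     mesh@triangles[, 2], mesh@triangles[, 3]), con)
  invisible(path)
}

#' Export a per-vertex field as CSV
#' @param field a [VertexField].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeVertexFieldCsv <- function(field, path) {
  utils::write.csv(data.frame(vertex = seq_along(field@values) - 1L,
                              value = field@values, known = field@known),
                   path, row.names = FALSE)
  invisible(path)
}
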