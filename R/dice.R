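#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)` over masks on the same grid. When both masks are
#' empty the score is 1 (perfect agreement of nothing); this keeps windowed
#' aggregation free of NaNs, and tissue-free windows are skipped upstream
#' anyway.
#'
#' @param a,b binary [GMMask2D]/[GMMask3D] pairs on identical grids, or
#'   plain logical/0-1 arrays of identical shape.
#' @return Dice score in \[0, 1\].
#' @export
setGeneric("dice", function(a, b) standardGeneric("dice"))

.diceArr <- function(x, y) {
  if (!identical(dim(as.array(x)), dim(as.array(y))))
    stop("dice: grid mismatch between masks")
  x <- x > 0.5; y <- y > 0.5
  sa <- sum(x); sb <- sum(y)
  if (sa + sb == 0) return(1)
  2 * sum(x & y) / (sa + sb)
}

#' @rdname dice
#' @export
setMethod("dice", signature("GMMask2D", "GMMask2D"), function(a, b) {
  if (!identical(dim(a@values), dim(b@values)))
    stop("dice: grid mismatch between masks")
  .diceArr(a@values, b@values)
})

#' @rdname dice
#' @export
setMethod("dice", signature("GMMask3D", "GMMask3D"), function(a, b) {
  if (!identical(dim(a@values), dim(b@values)))
    stop("dice: grid mismatch between masks")
  .diceArr(a@values, b@values)
})

#' @rdname dice
#' @export
setMethod("dice", signature("ANY", "ANY"), function(a, b)
  .diceArr(as.array(a), as.array(b)))

#' Michelson contrast of tissue pixel intensities
#'
#' `(Imax - Imin) / (Imax + Imin)` over pixels inside the tissue mask; 0 for
#' the degenerate all-zero case.
#'
#' @param img an [Image2D].
#' @param tissueMask a non-empty binary [GMMask2D] on the same grid.
#' @return contrast in \[0, 1\] for non-negative images.
#' @export
michelsonContrast <- function(img, tissueMask) {
  if (!identical(dim(img@values), dim(tissueMask@values)))
    stop("michelsonContrast: grid mismatch")
  sel <- tissueMask@values > 0.5
  if (!any(sel)) stop("michelsonContrast: empty tissue mask")
  v <- img@values[sel]
  lo <- min(v); hi <- max(v)
  if (hi + lo == 0) return(0)
  (hi - lo) / (hi + lo)
}
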