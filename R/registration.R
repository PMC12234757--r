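# In-package registration backends behind the narrow interface the
# pipeline needs: (i) rigid 2D alignment by centre-of-mass + rotation-grid
# initialisation and Nelder-Mead refinement of a mean-squared-difference
# metric on smoothed gray-matter masks; (ii) diffusion-regularised demons
# for the 2D and 3D deformable stages; (iii) a low-dof 3D affine optimised
# the same way. All alignment is mono-modal by construction (GM masks), so
# MSD is an appropriate metric. Every routine is deterministic for fixed
# inputs; Dice guards make each stage no-worse-than-identity.

.imageCOM <- function(img) {
  v <- pmax(img@values, 0)
  s <- sum(v)
  if (s == 0) return(img@origin + (dim(img@values) - 1) / 2 * img@spacing)
  r <- sum(row(v) * v) / s
  c <- sum(col(v) * v) / s
  .indexToWorld(c(r, c), img@origin, img@spacing)
}

.imageCenter <- function(img)
  img@origin + (dim(img@values) - 1) / 2 * img@spacing

.msd2 <- function(a, b) mean((a - b)^2)

# metric for a candidate rigid: resample moving through the rigid pull-back
# onto the fixed grid and compare
.rigidCost <- function(par, moving, fixed, center) {
  t <- Rigid2D(thetaDeg = par[1], translation = par[2:3], center = center)
  w <- applyTransform2D(moving, t, outGrid = fixed, mode = "linear")
  .msd2(w@values, fixed@values)
}

#' Rigid 2D registration of two section images
#'
#' Aligns `moving` to `fixed` by maximising similarity (minimising mean
#' squared difference after Gaussian smoothing, appropriate for the
#' mono-modal GM-mask images the pipeline aligns). Initialised from the
#' centre-of-mass offset and a coarse rotation sweep, refined by
#' Nelder-Mead at a downsampled then the native resolution. Deterministic
#' for fixed inputs.
#'
#' @param moving,fixed [Image2D] / [GMMask2D] objects with overlapping
#'   fields of view.
#' @param maxRotDeg rotation search range for the initial sweep (degrees).
#' @param blurSigmaPx Gaussian smoothing (pixels) applied to both images
#'   before matching; small blur makes binary masks differentiable.
#' @return a [Rigid2D] mapping moving into fixed space (centre = fixed
#'   image centre). Attribute `"converged"` is FALSE when the optimiser
#'   failed to improve on the identity, in which case the identity is
#'   returned with a warning flag rather than aborting.
#' @export
registerRigid2D <- function(moving, fixed, maxRotDeg = 15,
                            blurSigmaPx = 1) {
  mv <- Image2D(.gaussSmooth(moving@values, blurSigmaPx), moving@spacing,
                moving@origin)
  fx <- Image2D(.gaussSmooth(fixed@values, blurSigmaPx), fixed@spacing,
                fixed@origin)
  center <- .imageCenter(fx)
  t0 <- .imageCOM(fx) - .imageCOM(mv)

  # coarse level (factor 2) for the sweep and first refinement
  res2 <- 2 * max(fx@spacing)
  mv2 <- resampleImage2D(mv, res2); fx2 <- resampleImage2D(fx, res2)

  rotGrid <- seq(-maxRotDeg, maxRotDeg, by = 3)
  costs <- vapply(rotGrid, function(th)
    .rigidCost(c(th, t0), mv2, fx2, center), numeric(1))
  th0 <- rotGrid[which.min(costs)]

  p <- c(th0, t0)
  opt2 <- stats::optim(p, .rigidCost, moving = mv2, fixed = fx2,
                       center = center, method = "Nelder-Mead",
                       control = list(maxit = 150, reltol = 1e-8))
  opt1 <- stats::optim(opt2$par, .rigidCost, moving = mv, fixed = fx,
                       center = center, method = "Nelder-Mead",
                       control = list(maxit = 150, reltol = 1e-9))
  idCost <- .rigidCost(c(0, 0, 0), mv, fx, center)
  out <- Rigid2D(thetaDeg = opt1$par[1], translation = opt1$par[2:3],
                 center = center)
  converged <- is.finite(opt1$value) && opt1$value <= idCost + 1e-12
  if (!converged) out <- Rigid2D(center = center)
  attr(out, "converged") <- converged
  out
}

# ---- demons (2D) --------------------------------------------------------

.gradient2 <- function(m, spacing) {
  list((.shiftAxis(m, 1, -1) - .shiftAxis(m, 1, 1)) / (2 * spacing[1]),
       (.shiftAxis(m, 2, -1) - .shiftAxis(m, 2, 1)) / (2 * spacing[2]))
}

#' Deformable 2D registration (demons)
#'
#' Classic diffusion-regularised demons on mono-modal images: per-iteration
#' force `(F - M o phi) grad(M o phi) / (|grad|^2 + (F - M o phi)^2 / s^2)`,
#' fluid smoothing of the update, diffusion smoothing of the field.
#'
#' @param moving,fixed [Image2D]-like objects on the same grid.
#' @param iters demons iterations.
#' @param sigmaFluid,sigmaField Gaussian sigmas (pixels) for update/field
#'   smoothing.
#' @param stepMaxPx per-iteration displacement cap (pixels).
#' @return a [Deformation2D] `u` on the fixed grid: the registered moving
#'   image is `moving(x + u(x))`.
#' @export
demons2D <- function(moving, fixed, iters = 60L, sigmaFluid = 1,
                     sigmaField = 1, stepMaxPx = 1) {
  stopifnot(identical(dim(moving@values), dim(fixed@values)))
  sp <- fixed@spacing
  d <- dim(fixed@values)
  g <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  pts <- cbind(.indexToWorld(g$r, fixed@origin[1], sp[1]),
               .indexToWorld(g$c, fixed@origin[2], sp[2]))
  u1 <- matrix(0, d[1], d[2]); u2 <- matrix(0, d[1], d[2])
  F <- fixed@values
  s2 <- max(stats::sd(F), 0.1)^2
  for (it in seq_len(iters)) {
    src <- pts + cbind(as.numeric(u1), as.numeric(u2))
    ri <- .worldToIndex(src[, 1], moving@origin[1], moving@spacing[1])
    ci <- .worldToIndex(src[, 2], moving@origin[2], moving@spacing[2])
    W <- matrix(.bilinear2(moving@values, ri, ci), d[1], d[2])
    diffI <- F - W
    gr <- .gradient2(W, sp)
    den <- gr[[1]]^2 + gr[[2]]^2 + diffI^2 / s2
    den[den < 1e-12] <- 1e-12
    f1 <- diffI * gr[[1]] / den
    f2 <- diffI * gr[[2]] / den
    f1 <- .gaussSmooth(f1, sigmaFluid)
    f2 <- .gaussSmooth(f2, sigmaFluid)
    mag <- sqrt(f1^2 + f2^2)
    cap <- stepMaxPx * max(sp)
    scl <- ifelse(mag > cap, cap / mag, 1)
    u1 <- .gaussSmooth(u1 + f1 * scl, sigmaField)
    u2 <- .gaussSmooth(u2 + f2 * scl, sigmaField)
  }
  Deformation2D(list(u1, u2), spacing = sp, origin = fixed@origin)
}

#' Refine a section against its reference plane by 2D deformable alignment
#'
#' Runs demons between the section's current GM mask and the reference
#' plane's GM, guarded so the refinement never worsens the plane Dice: if
#' the reference plane is empty, or the warped Dice is below the unwarped
#' Dice, the identity field is returned with a flag.
#'
#' @param mask2d the section's current (chain-applied) GM mask on the
#'   reconstruction grid.
#' @param refPlane the corresponding reference-plane GM mask, same grid.
#' @param iters,sigmaFluid,sigmaField,stepMaxPx passed to [demons2D()].
#' @param rigidPre run a small rigid pre-alignment before the deformable
#'   stage (folded into the returned field).
#' @return a [Deformation2D]; attribute `"flagged"` TRUE when the identity
#'   was kept, attribute `"dice"` the per-section Dice after refinement.
#' @export
refine2D <- function(mask2d, refPlane, iters = 50L, sigmaFluid = 1,
                     sigmaField = 1, stepMaxPx = 1, rigidPre = TRUE) {
  d <- dim(mask2d@values)
  identity <- Deformation2D(list(matrix(0, d[1], d[2]),
                                 matrix(0, d[1], d[2])),
                            spacing = mask2d@spacing,
                            origin = mask2d@origin)
  d0 <- .diceArr(mask2d@values, refPlane@values)
  if (sum(refPlane@values > 0.5) == 0) {
    attr(identity, "flagged") <- TRUE
    attr(identity, "dice") <- d0
    return(identity)
  }
  # linear pre-alignment to the reference plane (absorbs residual rigid
  # offsets the 3D stage left), folded into the returned field; later
  # refinement passes start near-aligned and can skip it
  rig <- Rigid2D(center = .imageCenter(refPlane))
  pre <- mask2d
  if (rigidPre) {
    rigTry <- registerRigid2D(mask2d, refPlane, maxRotDeg = 6)
    if (isTRUE(attr(rigTry, "converged"))) {
      preTry <- applyTransform2D(mask2d, rigTry, outGrid = mask2d,
                                 mode = "linear")
      if (.diceArr(preTry@values, refPlane@values) >= d0) {
        rig <- rigTry
        pre <- preTry
      }
    }
  }
  mvS <- Image2D(.gaussSmooth(pre@values, 0.5), pre@spacing, pre@origin)
  fxS <- Image2D(.gaussSmooth(refPlane@values, 0.5), refPlane@spacing,
                 refPlane@origin)
  fld <- demons2D(mvS, fxS, iters = iters, sigmaFluid = sigmaFluid,
                  sigmaField = sigmaField, stepMaxPx = stepMaxPx)
  # compose: total pull-back = rigid^-1(x + u(x)) expressed as one field
  g <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  pts <- cbind(.indexToWorld(g$r, mask2d@origin[1], mask2d@spacing[1]),
               .indexToWorld(g$c, mask2d@origin[2], mask2d@spacing[2]))
  tot <- rigidPullback(rig, pts + .fieldAt2(fld, pts)) - pts
  fld <- Deformation2D(list(matrix(tot[, 1], d[1], d[2]),
                            matrix(tot[, 2], d[1], d[2])),
                       spacing = mask2d@spacing, origin = mask2d@origin)
  warped <- applyTransform2D(mask2d, fld, outGrid = mask2d, mode = "linear")
  d1 <- .diceArr(warped@values, refPlane@values)
  if (d1 < d0) {
    attr(identity, "flagged") <- TRUE
    attr(identity, "dice") <- d0
    return(identity)
  }
  attr(fld, "flagged") <- FALSE
  attr(fld, "dice") <- d1
  fld
}

# ---- affine / demons (3D) ----------------------------------------------

# homogeneous 4x4 pull-back affine: maps target-space points to source
.affineMatrix <- function(par, center) {
  rx <- .deg2rad(par[1]); ry <- .deg2rad(par[2]); rz <- .deg2rad(par[3])
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% diag(exp(par[7:9]))
  t <- par[4:6]
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center - A %*% center + t
  M
}

#' Apply a homogeneous 3D affine to points
#' @param M 4x4 affine matrix.
#' @param pts n x 3 point matrix.
#' @return n x 3 transformed points.
#' @export
applyAffine3D <- function(M, pts) {
  pts <- as.matrix(pts)
  sweep(pts %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
}

.volGridPoints <- function(v, stride = 1L) {
  d <- dim(v@values)
  ix <- seq(1L, d[1], by = stride); iy <- seq(1L, d[2], by = stride)
  iz <- seq(1L, d[3], by = stride)
  g <- expand.grid(x = ix, y = iy, z = iz)
  list(pts = cbind(.indexToWorld(g$x, v@origin[1], v@spacing[1]),
                   .indexToWorld(g$y, v@origin[2], v@spacing[2]),
                   .indexToWorld(g$z, v@origin[3], v@spacing[3])),
       idx = cbind(g$x, g$y, g$z))
}

.affineCost <- function(par, moving, fixed, center, pts, fvals) {
  M <- .affineMatrix(par, center)
  src <- applyAffine3D(M, pts)
  mean((fvals - sampleAt(moving, src, mode = "linear"))^2)
}

#' Affine 3D registration of two volumes
#'
#' Nine-parameter (rotation, translation, log-scale) alignment by
#' Nelder-Mead on the mean squared difference, centre-of-mass initialised,
#' evaluated on a strided voxel subset for speed.
#'
#' @param moving,fixed [Volume3D]-like fuzzy GM volumes.
#' @param stride metric evaluation stride (voxels).
#' @param maxit optimiser iterations per round.
#' @return 4x4 pull-back affine matrix (fixed -> moving coordinates).
#' @export
registerAffine3D <- function(moving, fixed, stride = 2L, maxit = 400L,
                             sweepDeg = 15) {
  comF <- .volumeCOM(fixed); comM <- .volumeCOM(moving)
  center <- fixed@origin + (dim(fixed@values) - 1) / 2 * fixed@spacing
  g <- .volGridPoints(fixed, stride)
  fvals <- fixed@values[g$idx]
  t0 <- comM - comF
  # coarse sweep over the rotation about the cutting axis (the dominant
  # unknown: the in-plane gauge of the chained stack)
  rotAxis <- fixed@cutAxis
  grid <- seq(-sweepDeg, sweepDeg, by = 2.5)
  sweepCost <- vapply(grid, function(th) {
    par <- c(0, 0, 0, t0, 0, 0, 0)
    par[rotAxis] <- th
    .affineCost(par, moving, fixed, center, g$pts, fvals)
  }, numeric(1))
  p0 <- c(0, 0, 0, t0, 0, 0, 0)
  p0[rotAxis] <- grid[which.min(sweepCost)]
  opt <- stats::optim(p0, .affineCost, moving = moving, fixed = fixed,
                      center = center, pts = g$pts, fvals = fvals,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8,
                                     parscale = c(2, 2, 2, 1, 1, 1,
                                                  0.05, 0.05, 0.05)))
  id <- .affineCost(c(0, 0, 0, 0, 0, 0, 0, 0, 0), moving, fixed, center,
                    g$pts, fvals)
  if (!is.finite(opt$value) || opt$value > id)
    return(structure(diag(4), converged = FALSE))
  structure(.affineMatrix(opt$par, center), converged = TRUE)
}

.volumeCOM <- function(v) {
  a <- pmax(v@values, 0)
  s <- sum(a)
  if (s == 0) return(v@origin + (dim(a) - 1) / 2 * v@spacing)
  d <- dim(a)
  ix <- sum(slice.index(a, 1) * a) / s
  iy <- sum(slice.index(a, 2) * a) / s
  iz <- sum(slice.index(a, 3) * a) / s
  .indexToWorld(c(ix, iy, iz), v@origin, v@spacing)
}

.gradient3 <- function(a, spacing) {
  list((.shiftAxis(a, 1, -1) - .shiftAxis(a, 1, 1)) / (2 * spacing[1]),
       (.shiftAxis(a, 2, -1) - .shiftAxis(a, 2, 1)) / (2 * spacing[2]),
       (.shiftAxis(a, 3, -1) - .shiftAxis(a, 3, 1)) / (2 * spacing[3]))
}

#' Deformable 3D registration (demons)
#'
#' @param moving,fixed [Volume3D]-like objects on the same grid.
#' @param iters demons iterations.
#' @param sigmaFluid,sigmaField smoothing sigmas (voxels).
#' @param stepMaxVox per-iteration displacement cap (voxels).
#' @return a [Deformation3D] on the fixed grid.
#' @export
demons3D <- function(moving, fixed, iters = 40L, sigmaFluid = 1,
                     sigmaField = 1, stepMaxVox = 1) {
  stopifnot(identical(dim(moving@values), dim(fixed@values)))
  sp <- fixed@spacing
  d <- dim(fixed@values)
  g <- .volGridPoints(fixed, 1L)
  pts <- g$pts
  u <- lapply(1:3, function(i) array(0, d))
  F <- fixed@values
  s2 <- max(stats::sd(F), 0.1)^2
  for (it in seq_len(iters)) {
    src <- pts + cbind(as.numeric(u[[1]]), as.numeric(u[[2]]),
                       as.numeric(u[[3]]))
    W <- array(sampleAt(moving, src, mode = "linear"), d)
    diffI <- F - W
    gr <- .gradient3(W, sp)
    den <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2 + diffI^2 / s2
    den[den < 1e-12] <- 1e-12
    cap <- stepMaxVox * max(sp)
    fs <- vector("list", 3)
    for (i in 1:3) fs[[i]] <- .gaussSmooth(diffI * gr[[i]] / den, sigmaFluid)
    mag <- sqrt(fs[[1]]^2 + fs[[2]]^2 + fs[[3]]^2)
    scl <- ifelse(mag > cap, cap / mag, 1)
    for (i in 1:3) u[[i]] <- .gaussSmooth(u[[i]] + fs[[i]] * scl, sigmaField)
  }
  Deformation3D(u, spacing = sp, origin = fixed@origin)
}

#' 3D registration of the reference GM volume to the reconstructed GM
#'
#' Affine stage followed by a deformable (demons) stage, both on the fuzzy
#' GM probability volumes. Guarded: the stage result is kept only while the
#' GM Dice (at threshold 0.5) does not decrease, so the output is always at
#' least as good as the identity; when the deformable stage diverges the
#' affine-only result is returned with a warning flag.
#'
#' @param moving the reference GM volume ([GMMask3D]/[Volume3D], fuzzy ok).
#' @param fixed the reconstructed GM volume on the target grid.
#' @param demonsIters,sigmaFluid,sigmaField demons settings.
#' @param stride affine metric stride.
#' @return list with `affine` (4x4 pull-back matrix), `field`
#'   ([Deformation3D] or NULL), `pullback` (function mapping fixed-space
#'   points to moving-space points), `aligned` (moving resampled onto the
#'   fixed grid), `dice` (before/affine/final), `flagged`.
#' @export
register3D <- function(moving, fixed, demonsIters = 40L, sigmaFluid = 1,
                       sigmaField = 1, stride = 2L) {
  g <- .volGridPoints(fixed, 1L)
  d <- dim(fixed@values)
  resampleWith <- function(pull) {
    src <- pull(g$pts)
    array(sampleAt(moving, src, mode = "linear"), d)
  }
  dice0 <- .diceArr(resampleWith(identity), fixed@values)

  M <- registerAffine3D(moving, fixed, stride = stride)
  pullA <- function(p) applyAffine3D(M, p)
  alignedA <- resampleWith(pullA)
  diceA <- .diceArr(alignedA, fixed@values)
  if (diceA < dice0) {
    M <- diag(4)
    pullA <- identity
    alignedA <- resampleWith(identity)
    diceA <- dice0
  }

  movA <- Volume3D(alignedA, spacing = fixed@spacing, origin = fixed@origin,
                   cutAxis = fixed@cutAxis)
  fld <- demons3D(movA, fixed, iters = demonsIters, sigmaFluid = sigmaFluid,
                  sigmaField = sigmaField)
  pullF <- function(p) pullA(p + .fieldAt3(fld, p))
  alignedF <- resampleWith(pullF)
  diceF <- .diceArr(alignedF, fixed@values)
  flagged <- FALSE
  if (diceF < diceA) {   # deformable stage diverged: keep affine only
    fld <- NULL
    pullF <- pullA
    alignedF <- alignedA
    diceF <- diceA
    flagged <- TRUE
  }
  list(affine = M, field = fld, pullback = pullF,
       aligned = Volume3D(alignedF, spacing = fixed@spacing,
                          origin = fixed@origin, cutAxis = fixed@cutAxis),
       dice = c(before = dice0, affine = diceA, final = diceF),
       flagged = flagged)
}

#' Map points from reconstruction space to reference space and back
#'
#' `register3D` returns the pull-back map (reconstruction -> reference).
#' The inverse (reference -> reconstruction), needed to carry reference
#' surfaces into slab space, is solved per point by fixed-point iteration
#' on `T(x) = p`.
#'
#' @param pullback the `pullback` function from [register3D()].
#' @param pts n x 3 points in reference space.
#' @param iters fixed-point iterations.
#' @return n x 3 points in reconstruction space.
#' @export
invertPullback <- function(pullback, pts, iters = 25L) {
  x <- as.matrix(pts)
  for (i in seq_len(iters)) x <- x - (pullback(x) - pts)
  x
}
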