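# Strain estimation: the 2D Savitzky-Golay first-derivative filter and its
# application to displacement fields.

#' Two-dimensional Savitzky-Golay derivative kernel
#'
#' The (2M+1) x (2M+1) kernel whose cross-correlation with a field returns
#' the least-squares slope along the column (second-index) axis, averaged
#' over 2M+1 rows. Every row equals
#' \deqn{h(x) = \frac{3x}{(2M+1)^2 M (M+1)\, GS}, \quad x = -M \dots M,}
#' which differentiates linear fields exactly (for M = 1, GS = 1 every row is
#' `c(-1/6, 0, 1/6)`).
#'
#' @param M filter half-width (>= 1).
#' @param gridStep grid step GS (physical distance between samples; use the
#'   pixel size for fields in metres, 1 for fields in pixel units).
#' @return A (2M+1) x (2M+1) kernel matrix.
#' @export
sgKernel <- function(M, gridStep = 1) {
  if (M < 1 || M != round(M)) stop("M must be an integer >= 1")
  if (gridStep <= 0) stop("gridStep must be > 0")
  row <- 3 * (-M:M) / ((2 * M + 1)^2 * M * (M + 1) * gridStep)
  matrix(rep(row, each = 2 * M + 1), nrow = 2 * M + 1)
}

#' Differentiate a 2D field along one axis
#'
#' Valid cross-correlation with the Savitzky-Golay kernel (transposed for the
#' axial direction); the M-pixel border where the window leaves the field is
#' NA.
#'
#' @param field numeric matrix (rows = axial z, cols = lateral x).
#' @param axis "x" differentiates along columns (lateral), "z" along rows
#'   (axial).
#' @param M filter half-width (default 5).
#' @param gridStep grid step GS (default 1).
#' @return Matrix of the same shape with an NA border of width M.
#' @export
strainComponent <- function(field, axis = c("x", "z"), M = 5, gridStep = 1) {
  axis <- match.arg(axis)
  if (any(dim(field) < 2 * M + 1))
    stop("field smaller than the ", 2 * M + 1, "-px filter support")
  # separable evaluation of the kernel cross-correlation (identical result)
  cpp_sg_derive(field, as.integer(M), gridStep, axis == "x")
}

#' Strain field of a displacement field
#'
#' Computes the four raw displacement-gradient components of Eq.-style
#' nabla-u: exx = dux/dx, exz = dux/dz, ezx = duz/dx, ezz = duz/dz. With
#' displacements in px and `gridStep = 1` the components are dimensionless.
#' Compression along z makes ezz negative (natural gradient sign); the
#' modulus stage takes magnitudes.
#'
#' @param field a [DisplacementField-class] (px units).
#' @param M Savitzky-Golay half-width (default 5, about 0.5 mm at
#'   0.045 mm/px).
#' @param gridStep grid step (default 1 for pixel-unit fields).
#' @return A [StrainField-class].
#' @export
computeStrain <- function(field, M = 5, gridStep = 1) {
  exx <- strainComponent(field@ux, "x", M, gridStep)
  exz <- strainComponent(field@ux, "z", M, gridStep)
  ezx <- strainComponent(field@uz, "x", M, gridStep)
  ezz <- strainComponent(field@uz, "z", M, gridStep)
  mask <- is.finite(ezz) & is.finite(exx)
  new("StrainField", exx = exx, exz = exz, ezx = ezx, ezz = ezz,
      validMask = mask,
      framePair = c(field@referenceIndex, field@targetIndex), M = as.integer(M))
}

#' Strain fields of a tracked sequence
#'
#' Cumulative pairing differentiates the frame-1 -> k cumulative fields (the
#' total strain entering the modulus computation); incremental pairing
#' differentiates the frame-to-frame difference of consecutive cumulative
#' fields (used by the performance descriptor's frame pairing).
#'
#' @param fields list of cumulative [DisplacementField-class] objects as
#'   returned by [trackSequence()].
#' @param pairing "cumulative" (default) or "incremental".
#' @param M,gridStep see [computeStrain()].
#' @return List of [StrainField-class] objects (one per tracked frame).
#' @export
strainSequence <- function(fields, pairing = c("cumulative", "incremental"),
                           M = 5, gridStep = 1) {
  pairing <- match.arg(pairing)
  if (!length(fields)) stop("no displacement fields")
  if (pairing == "cumulative")
    return(lapply(fields, computeStrain, M = M, gridStep = gridStep))
  zero <- displacementField(0 * fields[[1]]@ux, 0 * fields[[1]]@uz,
                            1L, 1L, cumulative = TRUE)
  prev <- c(list(zero), fields[-length(fields)])
  mapply(function(p, q) computeStrain(incrementalField(p, q), M = M,
                                      gridStep = gridStep),
         prev, fields, SIMPLIFY = FALSE)
}

#' Transport a per-frame map to the reference configuration
#'
#' Samples the map at the positions where the reference-frame material lands
#' (`out(x) = map(x + u(x))`), so framewise results computed in the deformed
#' configuration are expressed on the frame-1 pixel grid. Positions outside
#' the map are NA.
#'
#' @param map numeric matrix in target-frame coordinates.
#' @param field cumulative [DisplacementField-class] frame 1 -> target.
#' @return Matrix on the reference grid.
#' @export
warpFieldToReference <- function(map, field) {
  cpp_warp_bilinear(map, field@ux, field@uz)
}
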