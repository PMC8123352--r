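# Internal axial stress under a uniformly loaded rectangle: Love's
# closed-form half-space solution, an independent Boussinesq quadrature
# oracle, two-compressor superposition, and the uniform plane-stress
# baseline.

#' Solid angle subtended by a uniformly loaded rectangle
#'
#' The solid angle Omega under the rectangle [-a, a] x [-b, b] seen from the
#' interior point (x, y, z), z > 0, written as 2*pi minus four arccos corner
#' terms over the sign combinations (a -+ x)(b -+ y). Arccos arguments are
#' clamped to [-1, 1] against rounding.
#'
#' @param x,y,z observation point coordinates in m (vectorised; z > 0).
#' @param a,b rectangle half-width and half-depth in m.
#' @return Solid angle in steradian (2*pi directly under the load as z -> 0,
#'   0 far outside).
#' @export
loveOmega <- function(x, y, z, a, b) {
  if (any(z <= 0)) stop("z must be > 0")
  term <- function(sx, sy) {
    num <- (a + sx * x) * (b + sy * y)
    den <- sqrt(((a + sx * x)^2 + z^2) * ((b + sy * y)^2 + z^2))
    acos(pmin(pmax(num / den, -1), 1))
  }
  2 * pi - term(-1, -1) - term(-1, 1) - term(1, -1) - term(1, 1)
}

#' Axial stress of Love's solution for a uniformly loaded rectangle
#'
#' Evaluates \eqn{\sigma_{zz} = \frac{1}{2\pi}\left(\frac{\partial V}{\partial
#' z} - z\frac{\partial^2 V}{\partial z^2}\right)} for the Newtonian potential
#' V of a uniform pressure p on [-a, a] x [-b, b], with
#' \eqn{\partial V/\partial z = -p\,\Omega} and the corner-distance form of
#' the second derivative. The compressive magnitude is returned
#' (positive under load). z is floored at 1e-9 m so surface pixels evaluate
#' finitely.
#'
#' @param x,y,z observation point in m (vectorised).
#' @param a,b rectangle half-dimensions in m.
#' @param p applied pressure in Pa.
#' @return Compressive stress magnitude |sigma_zz| in Pa.
#' @examples
#' loveSigmaZz(0, 0, 1e-9, 19e-3, 4e-3, 635)  # -> 635 Pa under the load
#' @export
loveSigmaZz <- function(x, y, z, a, b, p) {
  z <- pmax(z, 1e-9)
  omega <- loveOmega(x, y, z, a, b)
  am <- a - x; ap <- a + x
  bm <- b - y; bp <- b + y
  # corner distances: a1 ~ (a-x, b-y), b2 ~ (a+x, b-y),
  #                   c3 ~ (a+x, b+y), d4 ~ (a-x, b+y)
  a1 <- sqrt(am^2 + bm^2 + z^2)
  b2 <- sqrt(ap^2 + bm^2 + z^2)
  c3 <- sqrt(ap^2 + bp^2 + z^2)
  d4 <- sqrt(am^2 + bp^2 + z^2)
  bracket <- am / (am^2 + z^2) * (bm / a1 + bp / d4) +
    ap / (ap^2 + z^2) * (bm / b2 + bp / c3) +
    bm / (bm^2 + z^2) * (am / a1 + ap / b2) +
    bp / (bp^2 + z^2) * (am / d4 + ap / c3)
  p / (2 * pi) * (omega + z * bracket)
}

#' Boussinesq quadrature oracle for the rectangular-load stress
#'
#' Numerically integrates the point-load kernel
#' \eqn{3pz^3/(2\pi R^5)} over the loaded rectangle with adaptive 2D
#' quadrature. Serves as an independent check of [loveSigmaZz()].
#'
#' @param x,y,z observation point in m (scalars; z > 0).
#' @param a,b rectangle half-dimensions in m.
#' @param p pressure in Pa.
#' @param reltol quadrature relative tolerance.
#' @return Stress magnitude in Pa.
#' @export
boussinesqSigmaZz <- function(x, y, z, a, b, p, reltol = 1e-8) {
  if (z <= 0) stop("z must be > 0")
  f <- function(xi, eta) {
    R2 <- (x - xi)^2 + (y - eta)^2 + z^2
    3 * p * z^3 / (2 * pi * R2^2.5)
  }
  q <- pracma::integral2(f, -a, a, -b, b, reltol = reltol)
  if (!is.finite(q$Q)) stop("quadrature did not converge")
  q$Q
}

imageGrid <- function(dim, geometry) {
  px <- geometry@pixelSize
  xs <- ((seq_len(dim[2]) - 0.5) - dim[2] / 2) * px
  zs <- (seq_len(dim[1]) - 0.5) * px
  list(x = matrix(rep(xs, each = dim[1]), nrow = dim[1]),
       z = matrix(rep(zs, dim[2]), nrow = dim[1]))
}

#' Love stress field of the top compressor on the image plane
#'
#' Evaluates [loveSigmaZz()] on the image grid (plane y = 0 through the
#' transducer's long axis; the image is laterally centred under the
#' transducer) with pressure p = F / A1.
#'
#' @param force applied force F in N.
#' @param geometry a [ScanGeometry-class].
#' @param dim image dimensions c(rows, cols).
#' @return A [StressField-class] (single compressor, assumption "love").
#' @export
loveStressField <- function(force, geometry, dim) {
  g <- imageGrid(dim, geometry)
  p <- force / contactArea(geometry)
  sig <- loveSigmaZz(g$x, 0, g$z, geometry@transducerWidth / 2,
                     geometry@transducerDepth / 2, p)
  new("StressField", sigmaZz = sig, pressure = p, geometry = geometry,
      assumption = "love")
}

#' Superpose the bottom-compressor reaction onto a top stress field
#'
#' The base plate acts as a second rectangular compressor carrying the same
#' force; its Love field (base rectangle dimensions, depth measured upward
#' from the bottom with pressure F / A1) is mirrored onto the image grid and
#' added scaled by A1 / A2:
#' \eqn{\sigma_{total} = \sigma_{top} + (A_1/A_2)\,\sigma_{bottom}}.
#'
#' @param sigmaTop a [StressField-class] of the top compressor.
#' @param force applied force F in N.
#' @param geometry a [ScanGeometry-class] (supplies base dimensions and
#'   specimen height).
#' @return A [StressField-class] with the superposed field.
#' @export
superposeCompressors <- function(sigmaTop, force, geometry) {
  dim <- dim(sigmaTop@sigmaZz)
  g <- imageGrid(dim, geometry)
  zb <- pmax(geometry@specimenHeight - g$z, 1e-9)
  p <- force / contactArea(geometry)
  bottom <- loveSigmaZz(g$x, 0, zb, geometry@baseWidth / 2,
                        geometry@baseDepth / 2, p)
  ratio <- contactArea(geometry) / baseArea(geometry)
  new("StressField", sigmaZz = sigmaTop@sigmaZz + ratio * bottom,
      pressure = sigmaTop@pressure, geometry = geometry, assumption = "love")
}

#' Two-compressor Love stress field
#'
#' Convenience wrapper: top-compressor Love field plus the scaled
#' bottom-compressor reaction.
#'
#' @inheritParams loveStressField
#' @return A [StressField-class].
#' @export
totalStressField <- function(force, geometry, dim) {
  superposeCompressors(loveStressField(force, geometry, dim), force, geometry)
}

#' Uniform plane-stress baseline field
#'
#' The comparison baseline sigma_zz = F / A1 everywhere.
#'
#' @inheritParams loveStressField
#' @return A [StressField-class] with assumption "plane".
#' @export
planeStressField <- function(force, geometry, dim) {
  p <- force / contactArea(geometry)
  new("StressField", sigmaZz = matrix(p, dim[1], dim[2]), pressure = p,
      geometry = geometry, assumption = "plane")
}
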