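# Scalar relations of the isotropic material model. Sign convention:
# compressive axial stress and strain enter as positive magnitudes.

#' Young's modulus from uniaxial stress and strain
#'
#' Computes E = sigma0 / eps0 under the uniform-axial-stress assumption, with
#' both quantities compressive-positive. Strains below `floor` yield NA
#' (masked) rather than a blown-up modulus.
#'
#' @param sigma0 axial stress magnitude, Pa (vectorised).
#' @param eps0 axial strain magnitude, dimensionless.
#' @param floor minimum |eps0| for a defined ratio (default 1e-4).
#' @return Modulus in Pa; NA where |eps0| < floor.
#' @examples
#' modulusFromStressStrain(1000, 0.1)   # 10000 Pa
#' modulusFromStressStrain(635, 0.05)   # 12700 Pa
#' @export
modulusFromStressStrain <- function(sigma0, eps0, floor = 1e-4) {
  out <- sigma0 / eps0
  out[!is.finite(eps0) | abs(eps0) < floor] <- NA_real_
  out
}

#' Strain-dependent apparent Young's modulus
#'
#' Exponential strain stiffening of a Veronda-Westmann-type material:
#' \eqn{E_{NL} = E e^{3\gamma\epsilon_0^2}}. Valid for small strains
#' (\eqn{\epsilon_0 \ll 1}); no hard failure outside that range.
#'
#' @param E linear Young's modulus, Pa.
#' @param eps0 axial strain magnitude.
#' @param gamma non-linearity parameter (>= 0).
#' @return Apparent modulus in Pa.
#' @examples
#' nonlinearModulus(10e3, 0.1, 10)  # 10 kPa * exp(0.3)
#' @export
nonlinearModulus <- function(E, eps0, gamma) {
  E * exp(3 * gamma * eps0^2)
}

#' Convert a two-dimensional to a three-dimensional Poisson's ratio
#'
#' The in-plane strain ratio observed on a 2D image section (nu') relates to
#' the three-dimensional Poisson's ratio by nu = nu' / (1 - nu').
#'
#' @param nuPrime two-dimensional Poisson's ratio (< 1); NA passes through.
#' @return Three-dimensional Poisson's ratio.
#' @examples
#' poisson2Dto3D(1 / 3)  # 0.5, incompressible limit
#' @export
poisson2Dto3D <- function(nuPrime) {
  if (any(nuPrime >= 1, na.rm = TRUE))
    stop("two-dimensional Poisson's ratio must be < 1")
  nuPrime / (1 - nuPrime)
}

#' Inverse of [poisson2Dto3D]
#'
#' @param nu three-dimensional Poisson's ratio.
#' @return The two-dimensional ratio nu / (1 + nu).
#' @export
poisson3Dto2D <- function(nu) {
  nu / (1 + nu)
}

#' Shear-wave speed of an elastic material
#'
#' Converts Young's modulus to the shear-wave speed
#' \eqn{c_t = \sqrt{E / (2\rho(1+\nu))} = \sqrt{G/\rho}} commonly reported by
#' clinical shear-wave elastography.
#'
#' @param E Young's modulus, Pa (vectorised).
#' @param nu Poisson's ratio.
#' @param rho density, kg/m^3 (default 1000).
#' @return Speed in m/s.
#' @examples
#' shearWaveSpeed(3e3, 0.5)  # 1 m/s
#' @export
shearWaveSpeed <- function(E, nu, rho = 1000) {
  sqrt(E / (2 * rho * (1 + nu)))
}
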