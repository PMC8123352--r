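# Mechanical reference estimators: bonded-block compression modulus and
# BASh (Bulychev-Alekhin-Shorshorov) indentation modulus, plus synthetic
# load-curve generators for round-trip validation.

#' Step-wise load curve
#'
#' @param displacements compressor positions in m, strictly increasing.
#' @param forces measured forces in N (>= 0).
#' @return A load-curve data.frame with class "LoadCurve".
#' @export
loadCurve <- function(displacements, forces) {
  if (length(displacements) != length(forces))
    stop("displacements and forces must have equal length")
  if (any(diff(displacements) <= 0))
    stop("displacements must strictly increase")
  if (any(!is.finite(forces)) || any(forces < 0))
    stop("forces must be finite and >= 0")
  structure(data.frame(displacement_m = displacements, force_n = forces),
            class = c("LoadCurve", "data.frame"))
}

#' Read a load-curve CSV (`displacement_m,force_n`)
#' @param path CSV file.
#' @return A [loadCurve()].
#' @export
readLoadCurve <- function(path) {
  df <- read.csv(path)
  if (!all(c("displacement_m", "force_n") %in% names(df)))
    stop("load curve must have columns displacement_m and force_n")
  loadCurve(df$displacement_m, df$force_n)
}

#' Indenter contact specification
#'
#' @param contactArea contact area A in m^2.
#' @param shapeFactor contact-area shape factor phi_c (default 1.016, the
#'   value for a rectangular indenter).
#' @return A list with class "IndenterSpec".
#' @export
indenterSpec <- function(contactArea, shapeFactor = 1.016) {
  if (contactArea <= 0) stop("contact area must be positive")
  if (shapeFactor < 1.0 || shapeFactor > 1.1)
    stop("shape factor must lie in [1.0, 1.1]")
  structure(list(contactArea = contactArea, shapeFactor = shapeFactor),
            class = "IndenterSpec")
}

#' Detect the contact point of a load curve
#'
#' First sample whose force reaches the contact threshold; displacements are
#' re-zeroed there by the downstream estimators.
#'
#' @param curve a [loadCurve()].
#' @param threshold contact force in N (default 0.1).
#' @return Index of the contact sample.
#' @export
detectContact <- function(curve, threshold = 0.1) {
  idx <- which(curve$force_n >= threshold)
  if (!length(idx))
    stop("load curve never reaches the contact threshold of ", threshold, " N")
  idx[1]
}

#' Compression modulus of a bonded block
#'
#' The bonded-rubber-block relation
#' \eqn{E = 3\sigma / ((\lambda^{-2} - \lambda) Z)} with shape factor
#' \eqn{Z = 1 + 2S^2} and stretch ratio \eqn{\lambda =} strained/unstrained
#' height. All post-contact points up to `maxStrain` are fitted by ordinary
#' least squares through the contact point (sigma against
#' \eqn{(\lambda^{-2}-\lambda)}), which recovers simulated curves exactly.
#'
#' @param curve a [loadCurve()].
#' @param height unstrained specimen height in m.
#' @param area loaded cross-section in m^2.
#' @param S ratio of one bonded to the force-free surface (default 0.139,
#'   the 25 x 25 mm face of a 45 mm block).
#' @param contactThreshold contact force in N (default 0.1).
#' @param maxStrain linear-region limit (default 0.15).
#' @return Young's modulus in Pa.
#' @export
compressionModulus <- function(curve, height, area, S = 0.139,
                               contactThreshold = 0.1, maxStrain = 0.15) {
  i0 <- detectContact(curve, contactThreshold)
  delta <- curve$displacement_m - curve$displacement_m[i0]
  force <- curve$force_n - curve$force_n[i0]
  keep <- seq_along(delta) >= i0
  lambda <- (height - delta) / height
  keep <- keep & lambda < 1 & (1 - lambda) <= maxStrain
  if (!any(keep)) stop("no usable compression points past contact")
  sigma <- force[keep] / area
  g <- lambda[keep]^-2 - lambda[keep]
  # sigma = E (lambda^-2 - lambda) Z / 3, so the OLS slope of sigma against
  # g = lambda^-2 - lambda (through the contact point) is E Z / 3
  slope <- sum(g * sigma) / sum(g^2)
  Z <- 1 + 2 * S^2
  3 * slope / Z
}

#' Indentation modulus via the BASh relation
#'
#' Contact stiffness from the post-contact slope dF/ddelta (ordinary least
#' squares through the contact point), converted by the generalised BASh
#' relation \eqn{dF/d\delta = (2/\sqrt\pi)\,\phi_c \sqrt{A}\, M_3'} and
#' \eqn{E = M_3' (1 - \nu^2)}.
#'
#' @param curve a [loadCurve()].
#' @param spec an [indenterSpec()].
#' @param nu Poisson's ratio (default 0.495).
#' @param contactThreshold contact force in N (default 0.1).
#' @return Young's modulus in Pa.
#' @export
indentationModulus <- function(curve, spec, nu = 0.495,
                               contactThreshold = 0.1) {
  i0 <- detectContact(curve, contactThreshold)
  if (nrow(curve) - i0 + 1 < 3)
    stop("need at least 3 post-contact points")
  delta <- curve$displacement_m[i0:nrow(curve)] - curve$displacement_m[i0]
  force <- curve$force_n[i0:nrow(curve)] - curve$force_n[i0]
  slope <- sum(delta * force) / sum(delta^2)
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive contact stiffness")
  M3 <- slope * sqrt(pi) / (2 * spec$shapeFactor * sqrt(spec$contactArea))
  M3 * (1 - nu^2)
}

#' Simulate a compression load curve
#'
#' Generates a step-wise bonded-block compression curve from the same model
#' the estimator inverts; optional Gaussian force noise.
#'
#' @param E Young's modulus in Pa.
#' @param height specimen height in m.
#' @param area loaded cross-section in m^2.
#' @param S bonded/free surface ratio.
#' @param nSteps number of compression steps (default 20).
#' @param stepWidth step width in m (default 0.2 mm).
#' @param noiseSd force noise standard deviation in N (default 0).
#' @return A [loadCurve()].
#' @export
simulateCompressionCurve <- function(E, height, area, S = 0.139, nSteps = 20,
                                     stepWidth = 0.2e-3, noiseSd = 0) {
  delta <- seq(0, nSteps * stepWidth, by = stepWidth)
  lambda <- (height - delta) / height
  Z <- 1 + 2 * S^2
  sigma <- E * (lambda^-2 - lambda) * Z / 3
  force <- sigma * area
  if (noiseSd > 0) force <- pmax(force + rnorm(length(force), 0, noiseSd), 0)
  loadCurve(delta, force)
}

#' Simulate an indentation load curve
#'
#' Linear post-contact force-displacement curve with the BASh contact
#' stiffness of the given indentation modulus.
#'
#' @param M3 indentation modulus M3' in Pa.
#' @param spec an [indenterSpec()].
#' @param nSteps number of steps (default 20).
#' @param stepWidth step width in m (default 0.2 mm).
#' @param noiseSd force noise standard deviation in N (default 0).
#' @return A [loadCurve()].
#' @export
simulateIndentationCurve <- function(M3, spec, nSteps = 20,
                                     stepWidth = 0.2e-3, noiseSd = 0) {
  stiffness <- 2 / sqrt(pi) * spec$shapeFactor * sqrt(spec$contactArea) * M3
  delta <- seq(0, nSteps * stepWidth, by = stepWidth)
  force <- stiffness * delta
  if (noiseSd > 0) force <- pmax(force + rnorm(length(force), 0, noiseSd), 0)
  loadCurve(delta, force)
}

#' Summarise repeated mechanical measurements
#'
#' Median, standard deviation and maximum relative difference across repeat
#' estimates (the layout of the reference-measurement result tables).
#'
#' @param estimates numeric vector of modulus estimates in Pa.
#' @return data.frame(median_Pa, sd_Pa, max_rel_diff_pct).
#' @export
mechrefSummary <- function(estimates) {
  med <- median(estimates)
  data.frame(median_Pa = med, sd_Pa = sd(estimates),
             max_rel_diff_pct = 100 * max(abs(estimates - med)) / med)
}
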