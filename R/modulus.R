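# Modulus, Poisson and shear-wave-speed maps, ROI definitions and summaries.

#' Regions of interest
#'
#' Rectangular or circular ROIs in physical image coordinates (m): x from the
#' left image edge, z from the transducer face.
#'
#' @param name ROI label.
#' @param x0,z0,x1,z1 rectangle corners in m.
#' @return An ROI description list.
#' @export
roiRect <- function(name, x0, z0, x1, z1) {
  list(name = name, shape = "rect", x0 = min(x0, x1), z0 = min(z0, z1),
       x1 = max(x0, x1), z1 = max(z0, z1))
}

#' @rdname roiRect
#' @param cx,cz,r circle centre and radius in m.
#' @export
roiCircle <- function(name, cx, cz, r) {
  list(name = name, shape = "circle", cx = cx, cz = cz, r = r)
}

#' Logical pixel mask of an ROI
#'
#' @param roi from [roiRect()] or [roiCircle()].
#' @param dim image dimensions c(rows, cols).
#' @param pixelSize pixel pitch in m/px.
#' @return Logical matrix.
#' @export
roiMask <- function(roi, dim, pixelSize) {
  xs <- (seq_len(dim[2]) - 0.5) * pixelSize
  zs <- (seq_len(dim[1]) - 0.5) * pixelSize
  X <- matrix(rep(xs, each = dim[1]), nrow = dim[1])
  Z <- matrix(rep(zs, dim[2]), nrow = dim[1])
  if (roi$shape == "rect")
    X >= roi$x0 & X <= roi$x1 & Z >= roi$z0 & Z <= roi$z1
  else
    (X - roi$cx)^2 + (Z - roi$cz)^2 <= roi$r^2
}

#' Per-frame Young's modulus map
#'
#' Divides the compressive stress magnitude by the cumulative axial strain
#' magnitude pixel-wise (uniform-axial-stress relation applied framewise).
#' With `gamma > 0` the exponential strain-stiffening factor
#' \eqn{e^{3\gamma\epsilon_0^2}} is divided out so the linear modulus is
#' reported. Pixels with |strain| below `strainFloor` are NA.
#'
#' @param strain a [StrainField-class] (cumulative).
#' @param stress a [StressField-class] from the same frame's force.
#' @param gamma non-linearity parameter (default 0).
#' @param strainFloor strain magnitude floor (default 1e-4).
#' @return Matrix of Young's modulus in Pa (NA where masked).
#' @export
frameModulusMap <- function(strain, stress, gamma = 0, strainFloor = 1e-4) {
  eps <- abs(strain@ezz)
  E <- modulusFromStressStrain(stress@sigmaZz, eps, floor = strainFloor)
  if (gamma > 0) E <- E / exp(3 * gamma * eps^2)
  E[!strain@validMask] <- NA_real_
  E
}

#' Pixelwise mean map over accepted frames
#'
#' Per-frame maps already live on the reference grid (cumulative-strain
#' wiring); maps computed in the deformed configuration should be passed
#' through [warpFieldToReference()] first. Returns the mean and the per-pixel
#' count of contributing frames.
#'
#' @param maps list of per-frame matrices on a common grid.
#' @param accepted indices of accepted frames.
#' @return `list(mean = <matrix>, count = <integer matrix>)`.
#' @export
meanModulusMap <- function(maps, accepted) {
  if (!length(accepted)) stop("no accepted frames to average")
  acc <- maps[accepted]
  s <- matrix(0, nrow(acc[[1]]), ncol(acc[[1]]))
  n <- matrix(0L, nrow(acc[[1]]), ncol(acc[[1]]))
  for (m in acc) {
    ok <- is.finite(m)
    s[ok] <- s[ok] + m[ok]
    n[ok] <- n[ok] + 1L
  }
  mean <- s / n
  mean[n == 0L] <- NA_real_
  list(mean = mean, count = n)
}

#' Poisson's ratio map from a strain field
#'
#' The two-dimensional ratio nu' = -(lateral strain)/(axial strain) is
#' converted to the three-dimensional Poisson's ratio nu = nu'/(1 - nu').
#' Pixels with axial strain below `strainFloor` or nu' >= 1 are NA; the
#' reported values are clipped to [0, 0.5].
#'
#' @param strain a [StrainField-class] (cumulative).
#' @param strainFloor axial strain magnitude floor (default 1e-4).
#' @return Matrix of the three-dimensional Poisson's ratio.
#' @export
poissonMap <- function(strain, strainFloor = 1e-4) {
  nuP <- -strain@exx / strain@ezz
  nuP[abs(strain@ezz) < strainFloor | !strain@validMask] <- NA_real_
  nuP[!is.na(nuP) & nuP >= 1] <- NA_real_
  nu <- nuP / (1 - nuP)
  pmin(pmax(nu, 0), 0.5)
}

#' ROI statistics of a map
#'
#' Median (the headline statistic), mean, standard deviation and pixel count
#' over the valid pixels of each ROI.
#'
#' @param map numeric matrix (NA outside the valid mask).
#' @param rois list of ROIs from [roiRect()]/[roiCircle()].
#' @param pixelSize pixel pitch in m/px.
#' @return data.frame(roi, n, median, mean, sd).
#' @export
roiSummary <- function(map, rois, pixelSize) {
  rows <- lapply(rois, function(roi) {
    sel <- map[roiMask(roi, dim(map), pixelSize)]
    sel <- sel[is.finite(sel)]
    if (!length(sel)) stop("ROI '", roi$name, "' contains no valid pixels")
    data.frame(roi = roi$name, n = length(sel), median = median(sel),
               mean = mean(sel), sd = if (length(sel) > 1) sd(sel) else 0)
  })
  do.call(rbind, rows)
}

#' Default ROI layout
#'
#' Homogeneous specimens use one central region; inclusion specimens use the
#' inclusion disc (slightly shrunk to avoid edge blur) plus two lateral body
#' rectangles at the inclusion depth.
#'
#' @param fov field of view c(width, height) in m.
#' @param inclusionCentre optional (x, z) inclusion centre in m.
#' @param inclusionRadius inclusion radius in m (0 for homogeneous).
#' @return List of ROIs.
#' @export
defaultRois <- function(fov, inclusionCentre = NULL, inclusionRadius = 0) {
  if (inclusionRadius <= 0) {
    return(list(roiRect("region1", 0.25 * fov[1], 0.2 * fov[2],
                        0.75 * fov[1], 0.6 * fov[2])))
  }
  cx <- inclusionCentre[1]; cz <- inclusionCentre[2]
  r <- inclusionRadius
  list(
    roiCircle("region2_inclusion", cx, cz, 0.6 * r),
    roiRect("region3a_body", 0.06 * fov[1], cz - r, cx - 1.6 * r, cz + r),
    roiRect("region3b_body", cx + 1.6 * r, cz - r, 0.94 * fov[1], cz + r)
  )
}
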