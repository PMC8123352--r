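#' Elastic material description
#'
#' Isotropic linear-elastic material with an optional exponential
#' strain-stiffening parameter (Veronda-Westmann-type apparent modulus
#' \eqn{E_{NL} = E e^{3\gamma\epsilon_0^2}}).
#'
#' @slot youngModulus Young's modulus in Pa (> 0).
#' @slot poissonRatio three-dimensional Poisson's ratio in [0, 0.5).
#' @slot gamma dimensionless non-linearity parameter (>= 0); 0 means linear.
#' @slot density mass density in kg/m^3 (used for shear-wave-speed conversion).
#' @export
setClass("ElasticMaterial",
  representation(youngModulus = "numeric", poissonRatio = "numeric",
                 gamma = "numeric", density = "numeric"),
  prototype(poissonRatio = 0.495, gamma = 0, density = 1000))

setValidity("ElasticMaterial", function(object) {
  msg <- character()
  if (length(object@youngModulus) != 1 || !is.finite(object@youngModulus) ||
      object@youngModulus <= 0)
    msg <- c(msg, "youngModulus must be a single positive finite value [Pa]")
  if (length(object@poissonRatio) != 1 || object@poissonRatio < 0 ||
      object@poissonRatio >= 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5)")
  if (length(object@gamma) != 1 || object@gamma < 0)
    msg <- c(msg, "gamma must be >= 0")
  if (length(object@density) != 1 || object@density <= 0)
    msg <- c(msg, "density must be positive")
  if (length(msg)) msg else TRUE
})

#' Create an elastic material
#'
#' @param youngModulus Young's modulus in Pa.
#' @param poissonRatio three-dimensional Poisson's ratio (default 0.495,
#'   near-incompressible soft tissue).
#' @param gamma non-linearity parameter of the apparent modulus (default 0).
#' @param density density in kg/m^3 (default 1000).
#' @return An [ElasticMaterial-class] object.
#' @examples
#' soft <- elasticMaterial(6920)
#' shearModulus(soft)
#' @export
elasticMaterial <- function(youngModulus, poissonRatio = 0.495, gamma = 0,
                            density = 1000) {
  new("ElasticMaterial", youngModulus = youngModulus,
      poissonRatio = poissonRatio, gamma = gamma, density = density)
}

#' Imaging and loading geometry
#'
#' Dimensions of the rectangular compressor (the transducer footprint), the
#' specimen base plate, the specimen height, and the image pixel size. The
#' image plane cuts the footprint through its long axis (y = 0); row index is
#' axial depth z (increasing away from the transducer face), column index is
#' lateral x.
#'
#' @slot transducerWidth footprint extent 2a along the image plane, m.
#' @slot transducerDepth footprint extent 2b across the image plane, m.
#' @slot baseWidth,baseDepth extent of the supporting base rectangle, m.
#' @slot specimenHeight distance from transducer face to base, m.
#' @slot pixelSize image pixel pitch, m/px.
#' @export
setClass("ScanGeometry",
  representation(transducerWidth = "numeric", transducerDepth = "numeric",
                 baseWidth = "numeric", baseDepth = "numeric",
                 specimenHeight = "numeric", pixelSize = "numeric"))

setValidity("ScanGeometry", function(object) {
  v <- c(object@transducerWidth, object@transducerDepth, object@baseWidth,
         object@baseDepth, object@specimenHeight, object@pixelSize)
  if (length(v) != 6 || any(!is.finite(v)) || any(v <= 0))
    return("all geometry lengths must be single positive values [m]")
  if (contactArea(object) > baseArea(object))
    return("transducer footprint area exceeds the base area")
  TRUE
})

#' Create a scan geometry
#'
#' Defaults reproduce the phantom-study configuration: 38 mm x 8 mm
#' transducer footprint on a 45 mm x 25 mm specimen of 25 mm height, imaged
#' at 0.045 mm/px.
#'
#' @param transducerWidth,transducerDepth footprint dimensions in m.
#' @param baseWidth,baseDepth base rectangle dimensions in m.
#' @param specimenHeight specimen height in m.
#' @param pixelSize pixel pitch in m/px.
#' @return A [ScanGeometry-class] object.
#' @examples
#' g <- scanGeometry()
#' contactArea(g) * 1e6  # mm^2
#' @export
scanGeometry <- function(transducerWidth = 38e-3, transducerDepth = 8e-3,
                         baseWidth = 45e-3, baseDepth = 25e-3,
                         specimenHeight = 25e-3, pixelSize = 0.045e-3) {
  new("ScanGeometry", transducerWidth = transducerWidth,
      transducerDepth = transducerDepth, baseWidth = baseWidth,
      baseDepth = baseDepth, specimenHeight = specimenHeight,
      pixelSize = pixelSize)
}

#' Ordered stack of grayscale B-mode frames
#'
#' @slot frames numeric array rows x cols x nframes, intensities in [0, 1];
#'   rows are axial depth, columns lateral position.
#' @slot pixelSize pixel pitch in m/px.
#' @slot times frame acquisition times in s, strictly increasing.
#' @export
setClass("CineSequence",
  representation(frames = "array", pixelSize = "numeric", times = "numeric"))

setValidity("CineSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be a rows x cols x nframes array")
  if (d[3] < 2) return("a CINE sequence needs at least 2 frames")
  if (length(object@times) != d[3]) return("one timestamp per frame required")
  if (any(diff(object@times) <= 0)) return("frame times must strictly increase")
  if (any(!is.finite(object@frames))) return("frame intensities must be finite")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a single positive value [m/px]")
  TRUE
})

#' Create a CINE sequence from an array of frames
#'
#' @param frames rows x cols x nframes array (or list of matrices).
#' @param pixelSize pixel pitch in m/px.
#' @param times frame times in s; derived from `frameRate` when missing.
#' @param frameRate frame rate in Hz used when `times` is missing.
#' @return A [CineSequence-class] object.
#' @export
cineSequence <- function(frames, pixelSize, times = NULL, frameRate = 43) {
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all frames must share the same shape")
    frames <- array(unlist(frames), dim = c(dims[1, 1], dims[2, 1], length(frames)))
  }
  if (is.null(times)) times <- (seq_len(dim(frames)[3]) - 1) / frameRate
  new("CineSequence", frames = frames, pixelSize = pixelSize, times = times)
}

#' Load-cell force log
#'
#' @slot times sample times in s, strictly increasing.
#' @slot forces forces in N.
#' @export
setClass("ForceLog", representation(times = "numeric", forces = "numeric"))

setValidity("ForceLog", function(object) {
  if (length(object@times) != length(object@forces) || length(object@times) < 2)
    return("times and forces must have equal length >= 2")
  if (any(diff(object@times) <= 0)) return("times must strictly increase")
  if (any(!is.finite(object@forces))) return("forces must be finite")
  TRUE
})

#' Create a force log
#'
#' @param times sample times in s.
#' @param forces forces in N.
#' @param maxForce plausibility bound in N (default 50); exceeding it errors.
#' @return A [ForceLog-class] object.
#' @export
forceLog <- function(times, forces, maxForce = 50) {
  if (any(forces < -maxForce | forces > maxForce))
    stop("force log outside the plausibility bound of ", maxForce, " N")
  new("ForceLog", times = as.numeric(times), forces = as.numeric(forces))
}

#' Dense displacement field between two frames
#'
#' Displacements are stored in pixels and sampled at the pixels of the
#' reference frame: the material imaged at reference pixel (i, j) appears at
#' (i + uz, j + ux) in the target frame. A cumulative field maps the target
#' frame back to the configuration of the first frame of the sequence.
#'
#' @slot ux,uz lateral and axial displacement components, px.
#' @slot referenceIndex,targetIndex 1-based frame indices.
#' @slot cumulative TRUE when the field accumulates from frame 1.
#' @export
setClass("DisplacementField",
  representation(ux = "matrix", uz = "matrix", referenceIndex = "integer",
                 targetIndex = "integer", cumulative = "logical"))

setValidity("DisplacementField", function(object) {
  if (!all(dim(object@ux) == dim(object@uz)))
    return("ux and uz must share the same shape")
  if (any(!is.finite(object@ux)) || any(!is.finite(object@uz)))
    return("displacement components must be finite")
  TRUE
})

displacementField <- function(ux, uz, referenceIndex = 1L, targetIndex = 2L,
                              cumulative = FALSE) {
  new("DisplacementField", ux = ux, uz = uz,
      referenceIndex = as.integer(referenceIndex),
      targetIndex = as.integer(targetIndex), cumulative = cumulative)
}

#' Displacement-gradient (strain) field
#'
#' The four raw gradient components of the displacement field (no
#' symmetrisation): exx = dux/dx, exz = dux/dz, ezx = duz/dx, ezz = duz/dz.
#' Entries closer than the filter half-width M to the border are NA and
#' excluded by `validMask`.
#'
#' @slot exx,exz,ezx,ezz dimensionless component matrices.
#' @slot validMask logical matrix, TRUE inside the valid convolution region.
#' @slot framePair the (reference, target) frame indices the field refers to.
#' @slot M Savitzky-Golay half-width used.
#' @export
setClass("StrainField",
  representation(exx = "matrix", exz = "matrix", ezx = "matrix", ezz = "matrix",
                 validMask = "matrix", framePair = "integer", M = "integer"))

#' Axial stress field on the image plane
#'
#' @slot sigmaZz compressive axial stress magnitude per pixel, Pa.
#' @slot pressure applied pressure F/A1 under the transducer, Pa.
#' @slot geometry the [ScanGeometry-class] used.
#' @slot assumption "love" (two-compressor Love solution) or "plane"
#'   (uniform stress).
#' @export
setClass("StressField",
  representation(sigmaZz = "matrix", pressure = "numeric",
                 geometry = "ScanGeometry", assumption = "character"))

#' Result container of the elastography pipeline
#'
#' @slot EMap mean Young's modulus map, Pa, on the reference grid.
#' @slot nuMap mean three-dimensional Poisson's ratio map.
#' @slot ctMap shear-wave-speed map, m/s.
#' @slot countMap per-pixel number of accepted frames entering the mean.
#' @slot framesUsed indices of the frames that passed the performance gates.
#' @slot performance per-frame descriptor log (frame, rho_i, rho_s, rho_e,
#'   p_S, p_E, accepted).
#' @slot trackLog reference-switch log of the displacement tracker.
#' @slot roiSummaries per-ROI statistics of the mean modulus map.
#' @slot manifest configuration snapshot that fully determines a rerun.
#' @export
setClass("ModulusResult",
  representation(EMap = "matrix", nuMap = "matrix", ctMap = "matrix",
                 countMap = "matrix", framesUsed = "integer",
                 performance = "data.frame", trackLog = "data.frame",
                 roiSummaries = "data.frame", manifest = "list"))

#' Synthetic phantom specification
#'
#' Describes a tissue-mimicking speckle phantom: a homogeneous body with an
#' optional stiffer cylindrical inclusion, compressed quasi-statically by the
#' transducer. Defaults emulate the gelatin phantom study conditions: 3 mm
#' compression at 1 mm/s, 43 frames/s, 25 mm x 25 mm field of view.
#'
#' @slot bodyMaterial,inclusionMaterial [ElasticMaterial-class]; the inclusion
#'   slot may be NULL for homogeneous phantoms.
#' @slot inclusionCentre (x, z) centre of the inclusion in m (image
#'   coordinates, x from the left edge).
#' @slot inclusionRadius inclusion radius in m (0 disables the inclusion).
#' @slot geometry [ScanGeometry-class].
#' @slot imageSize rows, cols of the rendered frames.
#' @slot compressionDepth total compression in m.
#' @slot compressionSpeed compression speed in m/s.
#' @slot frameRate frames per second.
#' @slot scattererDensity scatterers per pixel of the speckle texture.
#' @slot psfSigma Gaussian point-spread sigma in px.
#' @slot noiseSd additive Gaussian intensity noise (image range [0,1]).
#' @slot stressModel "love" for the depth-varying Love-consistent forward
#'   deformation, "uniform" for the uniform-axial-stress idealisation.
#' @slot seed integer seed controlling all randomness of the rendering.
#' @export
setClass("PhantomSpec",
  representation(bodyMaterial = "ElasticMaterial", inclusionMaterial = "ANY",
                 inclusionCentre = "numeric", inclusionRadius = "numeric",
                 geometry = "ScanGeometry", imageSize = "integer",
                 compressionDepth = "numeric", compressionSpeed = "numeric",
                 frameRate = "numeric", scattererDensity = "numeric",
                 psfSigma = "numeric", noiseSd = "numeric",
                 stressModel = "character", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@compressionDepth > 0.15 * object@geometry@specimenHeight)
    msg <- c(msg, "compression exceeds 15% of the specimen height")
  if (object@inclusionRadius > 0) {
    fov <- c(object@imageSize[2], object@imageSize[1]) * object@geometry@pixelSize
    cc <- object@inclusionCentre
    if (cc[1] - object@inclusionRadius < 0 || cc[1] + object@inclusionRadius > fov[1] ||
        cc[2] - object@inclusionRadius < 0 || cc[2] + object@inclusionRadius > fov[2])
      msg <- c(msg, "inclusion must lie inside the image")
    if (is.null(object@inclusionMaterial))
      msg <- c(msg, "inclusionRadius > 0 requires an inclusionMaterial")
  }
  if (!object@stressModel %in% c("love", "uniform"))
    msg <- c(msg, "stressModel must be 'love' or 'uniform'")
  if (length(msg)) msg else TRUE
})
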