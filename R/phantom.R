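# Tissue-mimicking phantom simulator: speckle texture, an analytic
# compression field consistent with the stress model the pipeline assumes,
# frame rendering by inverse mapping, and force curves consistent with the
# phantom's modulus field.

#' Create a phantom specification
#'
#' Defaults reproduce the gelatin phantom study conditions: a 25 mm x 25 mm
#' field of view compressed 3 mm at 1 mm/s, recorded at 43 frames/s. The
#' `"fast"` preset renders 256 x 256 px frames (coarser pixels over the same
#' field of view); `"full"` renders 556 x 556 px at 0.045 mm/px.
#'
#' @param bodyMaterial an [elasticMaterial()] for the body.
#' @param inclusionMaterial optional [elasticMaterial()] for a stiffer
#'   cylindrical inclusion.
#' @param inclusionRadius inclusion radius in m (default 4 mm when an
#'   inclusion material is given, 0 otherwise).
#' @param inclusionCentre (x, z) inclusion centre in m; defaults to the image
#'   centre.
#' @param preset "fast" (256 px) or "full" (556 px at 0.045 mm/px).
#' @param geometry a [ScanGeometry-class]; the pixel size is overridden to
#'   match the preset.
#' @param compressionDepth total compression in m (default 3 mm).
#' @param compressionSpeed compression speed in m/s (default 1 mm/s).
#' @param frameRate frames per second (default 43).
#' @param scattererDensity scatterers per pixel (default 0.15).
#' @param psfSigma Gaussian point-spread sigma in px (default 1.2).
#' @param noiseSd additive intensity noise (default 0.01).
#' @param stressModel "love" (default; the depth-varying two-compressor
#'   stress) or "uniform" (uniform axial stress idealisation).
#' @param seed integer seed for the rendering randomness.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(bodyMaterial = elasticMaterial(6920),
                        inclusionMaterial = NULL, inclusionRadius = NULL,
                        inclusionCentre = NULL, preset = c("fast", "full"),
                        geometry = scanGeometry(), compressionDepth = 3e-3,
                        compressionSpeed = 1e-3, frameRate = 43,
                        scattererDensity = 0.15, psfSigma = 1.2,
                        noiseSd = 0.01, stressModel = "love", seed = 1L) {
  preset <- match.arg(preset)
  n <- if (preset == "fast") 256L else 556L
  px <- if (preset == "fast") 25e-3 / 256 else 0.045e-3
  geometry@pixelSize <- px
  fov <- n * px
  if (is.null(inclusionRadius))
    inclusionRadius <- if (is.null(inclusionMaterial)) 0 else 4e-3
  if (is.null(inclusionCentre)) inclusionCentre <- c(fov / 2, fov / 2)
  new("PhantomSpec", bodyMaterial = bodyMaterial,
      inclusionMaterial = inclusionMaterial,
      inclusionCentre = inclusionCentre, inclusionRadius = inclusionRadius,
      geometry = geometry, imageSize = c(n, n),
      compressionDepth = compressionDepth,
      compressionSpeed = compressionSpeed, frameRate = frameRate,
      scattererDensity = scattererDensity, psfSigma = psfSigma,
      noiseSd = noiseSd, stressModel = stressModel, seed = as.integer(seed))
}

#' Ground-truth Young's modulus map of a phantom
#'
#' @param spec a [PhantomSpec-class].
#' @return Matrix of Young's modulus in Pa on the image grid.
#' @export
phantomModulusMap <- function(spec) {
  d <- spec@imageSize
  px <- spec@geometry@pixelSize
  E <- matrix(youngModulus(spec@bodyMaterial), d[1], d[2])
  if (spec@inclusionRadius > 0) {
    xs <- (seq_len(d[2]) - 0.5) * px
    zs <- (seq_len(d[1]) - 0.5) * px
    X <- matrix(rep(xs, each = d[1]), nrow = d[1])
    Z <- matrix(rep(zs, d[2]), nrow = d[1])
    incl <- (X - spec@inclusionCentre[1])^2 + (Z - spec@inclusionCentre[2])^2 <=
      spec@inclusionRadius^2
    E[incl] <- youngModulus(spec@inclusionMaterial)
  }
  E
}

#' Synthetic speckle frame
#'
#' Random point scatterers with log-normal amplitudes, splatted bilinearly
#' and convolved with a Gaussian point-spread function, normalised to [0, 1].
#' Deterministic given the seed.
#'
#' @param dim image dimensions c(rows, cols).
#' @param density scatterers per pixel.
#' @param psfSigma PSF standard deviation in px (0 keeps the raw impulses).
#' @param seed integer seed.
#' @return Intensity matrix in [0, 1].
#' @export
makeSpeckle <- function(dim, density = 0.15, psfSigma = 1.2, seed = 1L) {
  if (density <= 0) stop("density must be > 0")
  set.seed(seed)
  n <- max(1L, round(density * prod(dim)))
  zi <- runif(n, 0, dim[1] - 1)
  xi <- runif(n, 0, dim[2] - 1)
  amp <- rlnorm(n, 0, 0.5)
  img <- matrix(0, dim[1], dim[2])
  i0 <- floor(zi); j0 <- floor(xi)
  fz <- zi - i0; fx <- xi - j0
  for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    ii <- pmin(i0 + corner[1], dim[1] - 1) + 1
    jj <- pmin(j0 + corner[2], dim[2] - 1) + 1
    wz <- if (corner[1] == 0) 1 - fz else fz
    wx <- if (corner[2] == 0) 1 - fx else fx
    idx <- cbind(ii, jj)
    w <- amp * wz * wx
    for (k in seq_len(n)) img[idx[k, 1], idx[k, 2]] <- img[idx[k, 1], idx[k, 2]] + w[k]
  }
  if (psfSigma > 0) img <- cpp_gauss_blur(img, psfSigma)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  img
}

smoothLateral <- function(mat, sigmaPx) {
  if (sigmaPx <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigmaPx))
  k <- exp(-0.5 * ((-half):half)^2 / sigmaPx^2)
  k <- k / sum(k)
  nc <- ncol(mat)
  # reflect-pad columns, filter along the lateral (column) axis
  idx <- c(rev(seq_len(half) + 1), seq_len(nc), nc - seq_len(half))
  padded <- mat[, idx, drop = FALSE]
  out <- mat
  for (o in seq_along(k))
    if (o == 1) out <- k[1] * padded[, seq_len(nc)] else
      out <- out + k[o] * padded[, seq_len(nc) + (o - 1)]
  out
}

# per-pixel axial strain magnitude for applied pressure p; inverts
# eps * exp(3 gamma eps^2) = p sigHat / E by Newton when gamma > 0
phantomStrain <- function(sigHat, EMap, gammaMap, p) {
  rhs <- p * sigHat / EMap
  if (all(gammaMap == 0)) return(rhs)
  eps <- rhs
  for (it in 1:30) {
    f <- eps * exp(3 * gammaMap * eps^2) - rhs
    fp <- exp(3 * gammaMap * eps^2) * (1 + 6 * gammaMap * eps^2)
    eps <- eps - f / fp
  }
  eps
}

#' Analytic phantom displacement field
#'
#' Column-wise integration of the axial strain implied by the phantom's
#' stress model: per pixel, eps = sigma(x, z) / E(x, z) (with the optional
#' exponential stress-strain law when gamma > 0), with the bottom fixed and
#' lateral expansion at the two-dimensional ratio nu' = nu / (1 + nu). For
#' inclusion phantoms the strain field is laterally smoothed over about 1 mm
#' to avoid edge discontinuities. Displacements are returned in image
#' coordinates (depth measured from the moving transducer face), the frame in
#' which the tracker observes them.
#'
#' @param spec a [PhantomSpec-class].
#' @param compression applied compression in m.
#' @return List with `ux`, `uz` (px, image coordinates), `ezz`, `exx`
#'   (ground-truth gradients, natural signs), `pressure` (Pa), `force` (N)
#'   and `EMap` (Pa).
#' @export
phantomDisplacementField <- function(spec, compression) {
  if (compression > spec@compressionDepth + 1e-12)
    stop("compression exceeds the specified depth")
  d <- spec@imageSize
  px <- spec@geometry@pixelSize
  EMap <- phantomModulusMap(spec)
  gMap <- matrix(spec@bodyMaterial@gamma, d[1], d[2])
  if (spec@inclusionRadius > 0)
    gMap[EMap == youngModulus(spec@inclusionMaterial)] <-
      spec@inclusionMaterial@gamma
  jc <- ceiling(d[2] / 2)
  solvePressure <- function(sigCol, ECol, gCol, target) {
    # pressure whose column strain integral equals the target compression
    p <- target / (sum(sigCol / ECol) * px) # exact when gamma == 0
    if (any(gCol > 0)) {
      colInt <- function(q) sum(phantomStrain(sigCol, ECol, gCol, q)) * px
      for (it in 1:50) {
        g <- colInt(p) - target
        dg <- (colInt(p * (1 + 1e-6)) - colInt(p)) / (p * 1e-6)
        p <- p - g / dg
        if (abs(g) < 1e-14 * max(target, 1e-12)) break
      }
    }
    p
  }
  if (compression <= 0) {
    p <- 0
    eps <- matrix(0, d[1], d[2])
  } else if (spec@stressModel == "love") {
    # one pressure for the whole footprint, calibrated so the centre-column
    # surface displacement equals the applied compression
    sigHat <- totalStressField(contactArea(spec@geometry), spec@geometry,
                               d)@sigmaZz
    p <- solvePressure(sigHat[, jc], EMap[, jc], gMap[, jc], compression)
    eps <- phantomStrain(sigHat, EMap, gMap, p)
  } else {
    # rigid-compressor series springs: every column compresses by the same
    # amount, so the uniform-with-depth stress varies per column
    pcol <- vapply(seq_len(d[2]), function(j)
      solvePressure(rep(1, d[1]), EMap[, j], gMap[, j], compression),
      numeric(1))
    eps <- phantomStrain(matrix(1, d[1], d[2]), EMap, gMap,
                         matrix(rep(pcol, each = d[1]), nrow = d[1]))
    p <- mean(pcol)
  }
  if (spec@inclusionRadius > 0) eps <- smoothLateral(eps, 0.5e-3 / px)
  # axial displacement (lab frame, downward positive), bottom fixed:
  # uz_lab(z) = integral_z^H eps dz'
  below <- apply(eps[rev(seq_len(d[1])), , drop = FALSE], 2, cumsum)[rev(seq_len(d[1])), , drop = FALSE]
  uzLab <- (below - eps / 2) * px
  # lateral expansion about the image centre at ratio nu'
  nuP <- poisson3Dto2D(poissonRatio(spec@bodyMaterial))
  C <- t(apply(eps, 1, cumsum))
  S <- C - C[, jc] - (eps - eps[, jc]) / 2
  uxLab <- nuP * S * px
  # image coordinates: the frame moves with the transducer face, which has
  # descended by `compression`
  uzImg <- uzLab - compression
  list(ux = uxLab / px, uz = uzImg / px, ezz = -eps, exx = nuP * eps,
       pressure = p, force = p * contactArea(spec@geometry), EMap = EMap)
}

invertDisplacement <- function(ux, uz, nIter = 4) {
  wx <- ux; wz <- uz
  for (it in seq_len(nIter)) {
    sx <- cpp_warp_bilinear(ux, -wx, -wz)
    sz <- cpp_warp_bilinear(uz, -wx, -wz)
    sx[!is.finite(sx)] <- ux[!is.finite(sx)]
    sz[!is.finite(sz)] <- uz[!is.finite(sz)]
    wx <- sx; wz <- sz
  }
  list(wx = wx, wz = wz)
}

#' Render a synthetic CINE sequence with ground truth
#'
#' Warps a reference speckle frame by the analytic compression field of each
#' frame (inverse mapping with bilinear interpolation), adds Gaussian
#' intensity noise, and builds a force log consistent with the phantom's
#' modulus field (F = p A1, sampled at 100 Hz). Pixels that no material maps
#' to (the region below the descending bottom edge of the specimen) are dark.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with `cine` (a [CineSequence-class]), `forceLog` (a
#'   [ForceLog-class]), and `truth` (list: per-frame compressions `d`,
#'   per-frame `pressure` and `force`, final-frame `ux`/`uz`/`ezz`/`exx`,
#'   `EMap`, `nuPrime`, and the `spec`).
#' @export
renderSequence <- function(spec) {
  d <- spec@imageSize
  duration <- spec@compressionDepth / spec@compressionSpeed
  nf <- max(2L, ceiling(duration * spec@frameRate) + 1L)
  times <- (seq_len(nf) - 1) / spec@frameRate
  dk <- pmin(spec@compressionSpeed * times, spec@compressionDepth)
  ref <- makeSpeckle(d, spec@scattererDensity, spec@psfSigma, spec@seed)
  linear <- spec@bodyMaterial@gamma == 0 &&
    (spec@inclusionRadius == 0 || spec@inclusionMaterial@gamma == 0)
  full <- phantomDisplacementField(spec, spec@compressionDepth)
  frames <- array(0, dim = c(d[1], d[2], nf))
  set.seed(spec@seed + 1L)
  pressures <- numeric(nf)
  for (k in seq_len(nf)) {
    if (dk[k] <= 0) {
      fld <- list(ux = 0 * full$ux, uz = 0 * full$uz, pressure = 0)
    } else if (linear) {
      s <- dk[k] / spec@compressionDepth
      fld <- list(ux = s * full$ux, uz = s * full$uz,
                  pressure = s * full$pressure)
    } else {
      fld <- phantomDisplacementField(spec, dk[k])
    }
    pressures[k] <- fld$pressure
    inv <- invertDisplacement(fld$ux, fld$uz)
    img <- cpp_warp_bilinear(ref, -inv$wx, -inv$wz)
    img[!is.finite(img)] <- 0
    if (spec@noiseSd > 0)
      img <- img + rnorm(length(img), 0, spec@noiseSd)
    frames[, , k] <- pmin(pmax(img, 0), 1)
  }
  logT <- seq(0, duration + 0.05, by = 0.01)
  logP <- approx(times, pressures, xout = logT, rule = 2)$y
  truth <- list(d = dk, pressure = pressures,
                force = pressures * contactArea(spec@geometry),
                ux = full$ux, uz = full$uz, ezz = full$ezz, exx = full$exx,
                EMap = full$EMap,
                nuPrime = poisson3Dto2D(poissonRatio(spec@bodyMaterial)),
                spec = spec)
  list(cine = cineSequence(frames, pixelSize = spec@geometry@pixelSize,
                           times = times),
       forceLog = forceLog(logT, logP * contactArea(spec@geometry)),
       truth = truth)
}

#' Write a rendered phantom dataset to disk
#'
#' CINE stack as a 16-bit multipage TIFF, force log as CSV, ground-truth
#' modulus and strain maps as scaled float TIFFs, and a JSON metadata file.
#'
#' @param dataset result of [renderSequence()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCine(dataset$cine, file.path(dir, "cine.tif"))
  writeForceLog(dataset$forceLog, file.path(dir, "force.csv"))
  writeMapTiff(dataset$truth$EMap, file.path(dir, "truth_E.tif"))
  writeMapTiff(dataset$truth$ezz, file.path(dir, "truth_ezz.tif"))
  spec <- dataset$truth$spec
  jsonlite::write_json(list(
    pixel_size_m = spec@geometry@pixelSize,
    frame_rate_hz = spec@frameRate,
    compression_depth_m = spec@compressionDepth,
    compression_speed_m_s = spec@compressionSpeed,
    stress_model = spec@stressModel,
    body_E_Pa = youngModulus(spec@bodyMaterial),
    inclusion_E_Pa = if (spec@inclusionRadius > 0)
      youngModulus(spec@inclusionMaterial) else NULL,
    inclusion_radius_m = spec@inclusionRadius,
    seed = spec@seed), file.path(dir, "meta.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
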