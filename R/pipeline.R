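# End-to-end orchestration: tracking -> strain -> stress -> performance
# gating -> modulus, Poisson and shear-wave maps with ROI summaries.

#' Run configuration
#'
#' Collects the tunable parameters of the elastography pipeline with their
#' study defaults.
#'
#' @param rhoMin correlation threshold for reference-frame redefinition
#'   (default 0.9).
#' @param pMin minimum performance descriptor (default 0.9).
#' @param M Savitzky-Golay half-width in px (default 5).
#' @param backend dense-flow backend, see [flowBackends()].
#' @param blurSigma preprocessing Gaussian blur in px (default 1).
#' @param gamma non-linearity parameter divided out of the modulus maps
#'   (default 0, linear).
#' @param nu assumed three-dimensional Poisson's ratio for the shear-wave
#'   conversion (default 0.495).
#' @param density density in kg/m^3 for the shear-wave conversion.
#' @param strainFloor minimum |strain| for a defined modulus (default 1e-4).
#' @param stressAssumption "love" (default) or "plane".
#' @param geometry a [ScanGeometry-class].
#' @param rois optional ROI list ([roiRect()]/[roiCircle()]); a central
#'   region is used when NULL.
#' @param compose displacement accumulation mode, "warp" or "add".
#' @param seed integer seed recorded in the manifest.
#' @return A validated configuration list of class "RunConfig".
#' @export
runConfig <- function(rhoMin = 0.9, pMin = 0.9, M = 5,
                      backend = "lucaskanade", blurSigma = 1, gamma = 0,
                      nu = 0.495, density = 1000, strainFloor = 1e-4,
                      stressAssumption = c("love", "plane"),
                      geometry = scanGeometry(), rois = NULL,
                      compose = c("warp", "add"), seed = 1L) {
  stressAssumption <- match.arg(stressAssumption)
  compose <- match.arg(compose)
  if (rhoMin <= 0 || rhoMin > 1) stop("rhoMin must lie in (0, 1]")
  if (pMin < 0 || pMin > 1) stop("pMin must lie in [0, 1]")
  if (M < 1 || M != round(M)) stop("M must be an integer >= 1")
  if (!backend %in% flowBackends())
    stop("unknown backend '", backend, "'; available: ",
         paste(flowBackends(), collapse = ", "))
  structure(list(rhoMin = rhoMin, pMin = pMin, M = as.integer(M),
                 backend = backend, blurSigma = blurSigma, gamma = gamma,
                 nu = nu, density = density, strainFloor = strainFloor,
                 stressAssumption = stressAssumption, geometry = geometry,
                 rois = rois, compose = compose, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the elastography pipeline
#'
#' Executes the full workflow on a CINE sequence and its force log: dense
#' displacement tracking with reference redefinition, Savitzky-Golay strain,
#' the per-frame stress field from the resampled force, per-frame modulus
#' maps, performance gating, and the mean modulus / Poisson / shear-wave maps
#' with ROI summaries. All maps live on the frame-1 (reference) pixel grid.
#'
#' @param cine a [CineSequence-class].
#' @param force a [ForceLog-class], or a numeric vector of forces per frame
#'   (N).
#' @param config a [runConfig()].
#' @return A [ModulusResult-class].
#' @export
runElastography <- function(cine, force, config = runConfig()) {
  t0 <- proc.time()[["elapsed"]]
  geometry <- config$geometry
  geometry@pixelSize <- pixelSize(cine)
  forces <- if (is(force, "ForceLog"))
    resampleForceToFrames(force, frameTimes(cine)) else force
  if (length(forces) != nFrames(cine))
    stop("stress stage: need one force per frame")
  dims <- dim(getFrame(cine, 1))

  track <- tryCatch(
    trackSequence(cine, rhoMin = config$rhoMin, backend = config$backend,
                  blurSigma = config$blurSigma, compose = config$compose),
    error = function(e) stop("tracking stage: ", conditionMessage(e),
                             call. = FALSE))
  tTrack <- proc.time()[["elapsed"]]

  strains <- tryCatch(
    strainSequence(track$fields, pairing = "cumulative", M = config$M),
    error = function(e) stop("strain stage: ", conditionMessage(e),
                             call. = FALSE))
  # Love's solution is homogeneous of degree 1 in the pressure, so the unit
  # field is evaluated once and scaled by each frame's force
  unitField <- if (config$stressAssumption == "love")
    totalStressField(1, geometry, dims)
  else planeStressField(1, geometry, dims)
  stressFor <- function(k) {
    new("StressField", sigmaZz = unitField@sigmaZz * forces[k],
        pressure = unitField@pressure * forces[k], geometry = geometry,
        assumption = unitField@assumption)
  }
  EMaps <- lapply(seq_along(strains), function(i)
    frameModulusMap(strains[[i]], stressFor(i + 1L), gamma = config$gamma,
                    strainFloor = config$strainFloor))
  nuMaps <- lapply(strains, poissonMap, strainFloor = config$strainFloor)
  tMaps <- proc.time()[["elapsed"]]

  # image maps on the reference grid for the descriptor pairings
  imgs <- lapply(seq_len(nFrames(cine)), function(k)
    preprocessFrame(getFrame(cine, k), config$blurSigma))
  imageMaps <- lapply(seq_along(track$fields), function(i)
    warpImage(imgs[[i + 1L]], track$fields[[i]]))
  strainMaps <- lapply(strains, slot, "ezz")
  perf <- framePerformance(imageMaps, strainMaps, EMaps, pMin = config$pMin)
  accepted <- tryCatch(gateFrames(perf, pMin = config$pMin, "elastography"),
                       error = function(e) stop("performance stage: ",
                                                conditionMessage(e),
                                                call. = FALSE))

  Emean <- meanModulusMap(EMaps, accepted)
  numean <- meanModulusMap(nuMaps, accepted)
  ct <- shearWaveSpeed(Emean$mean, config$nu, config$density)
  fov <- rev(dims) * pixelSize(cine)
  rois <- if (is.null(config$rois)) defaultRois(fov) else config$rois
  summaries <- roiSummary(Emean$mean, rois, pixelSize(cine))
  tEnd <- proc.time()[["elapsed"]]

  manifest <- list(
    backend = track$backend, stressAssumption = config$stressAssumption,
    rhoMin = config$rhoMin, pMin = config$pMin, M = config$M,
    blurSigma = config$blurSigma, gamma = config$gamma, nu = config$nu,
    strainFloor = config$strainFloor, seed = config$seed,
    pixelSize = pixelSize(cine), imageDim = dims, nFrames = nFrames(cine),
    referenceSwitches = track$log$frame[track$log$switched],
    rois = rois,
    timings = c(tracking = tTrack - t0, maps = tMaps - tTrack,
                gating_and_summary = tEnd - tMaps),
    package = as.character(utils::packageVersion("elastoflow")))
  # frame indices in CINE numbering (tracked frame i is CINE frame i + 1)
  new("ModulusResult", EMap = Emean$mean, nuMap = numean$mean, ctMap = ct,
      countMap = Emean$count, framesUsed = as.integer(accepted + 1L),
      performance = perf, trackLog = track$log, roiSummaries = summaries,
      manifest = manifest)
}

#' Write the standard result files of a pipeline run
#'
#' Float-TIFF maps (E, nu, ct), the ROI CSV report, the performance CSV and
#' a JSON manifest.
#'
#' @param result a [ModulusResult-class].
#' @param dir output directory (created if missing).
#' @param specimen specimen label used in the ROI report.
#' @return `dir`, invisibly.
#' @export
writeResult <- function(result, dir, specimen = "specimen") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMapTiff(result@EMap, file.path(dir, "young_modulus_Pa.tif"))
  writeMapTiff(result@nuMap, file.path(dir, "poisson_ratio.tif"))
  writeMapTiff(result@ctMap, file.path(dir, "shear_wave_speed_m_s.tif"))
  writeRoiReport(result@roiSummaries, file.path(dir, "roi_report.csv"),
                 specimen = specimen,
                 nFramesUsed = length(result@framesUsed))
  writePerformanceLog(result@performance, file.path(dir, "performance.csv"))
  jsonlite::write_json(result@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
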