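# Reading CINE stacks and force logs, writing maps and reports.
# CINE dialect: a multipage TIFF, a single directory of ordered PNG/TIFF
# frames, or an explicit vector of frame files. Force CSV dialect: columns
# `time_s,force_n`, header required, '.' decimal separator.

luminance <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (dim(img)[3] >= 3) {
    message("RGB input converted to grayscale by luminance")
    return(0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3])
  }
  img[, , 1]
}

readFrameFile <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
    else tiff::readTIFF(path)
  }, error = function(e) stop("cannot read frame '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  luminance(img)
}

#' Read a CINE sequence
#'
#' @param path a multipage TIFF file, a directory of PNG/TIFF frames (sorted
#'   by name), or a character vector of frame files in order.
#' @param pixelSize pixel pitch in m/px.
#' @param frameRate frame rate in Hz used to assign timestamps (default 43).
#' @param times explicit frame times in s, overriding `frameRate`.
#' @return A [CineSequence-class].
#' @export
readCine <- function(path, pixelSize, frameRate = 43, times = NULL) {
  if (length(path) == 1 && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
    if (!length(path)) stop("no PNG/TIFF frames found in directory")
  }
  if (length(path) == 1) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("cannot read CINE stack '", path,
                                               "': ", conditionMessage(e),
                                               call. = FALSE))
    frames <- lapply(pages, luminance)
  } else {
    frames <- lapply(path, readFrameFile)
  }
  if (length(frames) < 2) stop("a CINE sequence needs at least 2 frames")
  shapes <- vapply(frames, dim, integer(2))
  bad <- which(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])
  if (length(bad))
    stop("frame ", bad[1], " has shape ", shapes[1, bad[1]], "x",
         shapes[2, bad[1]], " but frame 1 has ", shapes[1, 1], "x", shapes[2, 1])
  cineSequence(frames, pixelSize = pixelSize, times = times,
               frameRate = frameRate)
}

#' Write a CINE sequence as a multipage TIFF
#'
#' Integer pixel types round-trip bit-identically through
#' [readCine()]/[writeCine()].
#'
#' @param cine a [CineSequence-class].
#' @param path output TIFF file.
#' @param bitsPerSample 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
writeCine <- function(cine, path, bitsPerSample = 16L) {
  frames <- lapply(seq_len(nFrames(cine)), function(k) {
    f <- getFrame(cine, k)
    pmin(pmax(f, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bitsPerSample,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a force log CSV
#'
#' Expects a header `time_s,force_n` with '.' decimal separator.
#'
#' @param path CSV file.
#' @param maxForce plausibility bound in N (default 50).
#' @return A [ForceLog-class].
#' @export
readForceLog <- function(path, maxForce = 50) {
  df <- read.csv(path)
  if (!all(c("time_s", "force_n") %in% names(df)))
    stop("force log must have columns time_s and force_n")
  forceLog(df$time_s, df$force_n, maxForce = maxForce)
}

#' Write a force log CSV
#' @param log a [ForceLog-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeForceLog <- function(log, path) {
  write.csv(data.frame(time_s = log@times, force_n = log@forces), path,
            row.names = FALSE)
  invisible(path)
}

#' Resample a force log to frame times
#'
#' Linear interpolation between log samples; constant extrapolation at the
#' ends (with a warning naming the affected frames).
#'
#' @param log a [ForceLog-class].
#' @param frameTimes frame times in s.
#' @return Force per frame, N.
#' @examples
#' lg <- forceLog(c(0, 1), c(0, 2))
#' resampleForceToFrames(lg, 0.5)  # 1 N
#' @export
resampleForceToFrames <- function(log, frameTimes) {
  if (length(log@times) < 2) stop("empty or degenerate force log")
  outside <- frameTimes < min(log@times) | frameTimes > max(log@times)
  if (any(outside))
    warning(sum(outside), " frame time(s) outside the force log; ",
            "using constant extrapolation")
  approx(log@times, log@forces, xout = frameTimes, rule = 2)$y
}

#' Write a 2D map as a scaled 32-bit float TIFF with a JSON sidecar
#'
#' The map is stored scaled into [0, 1]; the affine scale (`offset`,
#' `scale`, so that value = offset + scale * stored) and the NA fill value
#' are recorded in `<path>.json`. [readMapTiff()] reverses the scaling.
#'
#' @param map numeric matrix (NA allowed).
#' @param path output TIFF file.
#' @return `path`, invisibly.
#' @export
writeMapTiff <- function(map, path) {
  rng <- range(map, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  stored <- (map - rng[1]) / scale
  stored[is.na(stored)] <- 0
  tiff::writeTIFF(stored, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            na_mask = which(is.na(map))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [writeMapTiff()]
#' @param path TIFF file with its JSON sidecar.
#' @return Numeric matrix with NAs restored.
#' @export
readMapTiff <- function(path) {
  stored <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- meta$offset + meta$scale * stored
  if (length(meta$na_mask)) out[meta$na_mask] <- NA_real_
  out
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [runConfig()]; unknown keys error.
#'
#' @param path YAML file.
#' @return A run configuration list (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

#' Write the ROI report CSV
#'
#' Columns: `specimen,roi,median_E_Pa,mean_E_Pa,std_E_Pa,n_px,n_frames_used`.
#'
#' @param summaries data.frame from [roiSummary()].
#' @param path output CSV file.
#' @param specimen specimen label.
#' @param nFramesUsed number of accepted frames.
#' @return `path`, invisibly.
#' @export
writeRoiReport <- function(summaries, path, specimen = "specimen",
                           nFramesUsed = NA_integer_) {
  df <- data.frame(specimen = specimen, roi = summaries$roi,
                   median_E_Pa = summaries$median, mean_E_Pa = summaries$mean,
                   std_E_Pa = summaries$sd, n_px = summaries$n,
                   n_frames_used = nFramesUsed)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-frame performance log CSV
#'
#' Columns: `frame,rho_i,rho_s,rho_e,p_S,p_E,accepted`.
#'
#' @param performance data.frame as stored in a [ModulusResult-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writePerformanceLog <- function(performance, path) {
  write.csv(performance, path, row.names = FALSE)
  invisible(path)
}
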