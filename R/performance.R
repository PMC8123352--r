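# Per-frame trustability descriptors and frame gating. The strain descriptor
# p_S = rho_i * rho_s combines the correlations of consecutive image and
# strain data; the elastography descriptor p_E = rho_i * rho_s * rho_e adds
# the correlation of consecutive modulus maps.

#' Correlation between consecutive stage maps
#'
#' Computes the 2D Pearson correlation between a map of the previous frame
#' and the current frame's map, optionally warped onto the previous
#' configuration first. Maps already co-registered on the reference grid
#' (cumulative-strain wiring) are compared directly. An empty valid
#' intersection yields NA (the frame is then rejected by the gate).
#'
#' @param prevMap,currMap numeric matrices (NA allowed).
#' @param field optional [DisplacementField-class] used to warp `currMap`
#'   onto the previous configuration before correlating.
#' @return Correlation in [-1, 1], or NA when undefined.
#' @export
stageCorrelation <- function(prevMap, currMap, field = NULL) {
  if (!is.null(field)) currMap <- warpImage(currMap, field)
  tryCatch(frameCorrelation(prevMap, currMap), error = function(e) NA_real_)
}

#' Build the per-frame performance table
#'
#' Frame pairings are formed dynamically: each frame is compared with the
#' last frame that passed the gate; when that pairing fails, the immediately
#' preceding frame is tried as a fallback partner before the frame is
#' discarded, so a single corrupted frame rejects exactly itself and an
#' untrustworthy early pairing base cannot block the whole sequence. Gating
#' is sequential: the strain gate p_S = rho_i * rho_s >= pMin must pass
#' before the elastography descriptor p_E = p_S * rho_e is evaluated.
#'
#' @param imageMaps list of per-frame image maps on a common grid (index 1 =
#'   first tracked frame, which serves as the initial pairing base and is not
#'   itself gated).
#' @param strainMaps list of per-frame strain maps (same indexing).
#' @param modulusMaps list of per-frame modulus maps.
#' @param pMin minimum performance (default 0.9).
#' @return data.frame with columns frame, paired_with, rho_i, rho_s, rho_e,
#'   p_S, p_E, accepted. `frame` indexes the lists.
#' @export
framePerformance <- function(imageMaps, strainMaps, modulusMaps, pMin = 0.9) {
  n <- length(imageMaps)
  stopifnot(length(strainMaps) == n, length(modulusMaps) == n)
  rec <- data.frame(frame = seq_len(n), paired_with = NA_integer_,
                    rho_i = NA_real_, rho_s = NA_real_, rho_e = NA_real_,
                    p_S = NA_real_, p_E = NA_real_, accepted = FALSE)
  evalPair <- function(base, k) {
    ri <- stageCorrelation(imageMaps[[base]], imageMaps[[k]])
    rs <- stageCorrelation(strainMaps[[base]], strainMaps[[k]])
    pS <- ri * rs
    re <- pE <- NA_real_
    if (!is.na(pS) && pS >= pMin) {
      re <- stageCorrelation(modulusMaps[[base]], modulusMaps[[k]])
      pE <- pS * re
    }
    list(base = base, rho_i = ri, rho_s = rs, rho_e = re, p_S = pS, p_E = pE,
         ok = !is.na(pE) && pE >= pMin)
  }
  last <- 1L
  for (k in seq_len(n)[-1]) {
    att <- evalPair(last, k)
    if (!att$ok && last != k - 1L) {
      fallback <- evalPair(k - 1L, k)
      if (fallback$ok) att <- fallback
    }
    rec$paired_with[k] <- att$base
    rec$rho_i[k] <- att$rho_i
    rec$rho_s[k] <- att$rho_s
    rec$rho_e[k] <- att$rho_e
    rec$p_S[k] <- att$p_S
    rec$p_E[k] <- att$p_E
    if (att$ok) {
      rec$accepted[k] <- TRUE
      last <- k
    }
  }
  rec
}

#' Gate frames on a performance descriptor
#'
#' The strain stage gates on p_S, the elastography stage on p_E. Raising
#' `pMin` never enlarges the accepted set.
#'
#' @param records data.frame with columns p_S and p_E (see
#'   [framePerformance()]).
#' @param pMin minimum performance (default 0.9).
#' @param stage "strain" or "elastography".
#' @return Integer indices of the accepted frames.
#' @export
gateFrames <- function(records, pMin = 0.9, stage = c("strain", "elastography")) {
  stage <- match.arg(stage)
  p <- if (stage == "strain") records$p_S else records$p_E
  idx <- which(!is.na(p) & p >= pMin)
  if (!length(idx))
    stop("no frame passed the ", stage, " performance gate (pMin = ", pMin,
         "); best p = ", signif(max(p, na.rm = TRUE), 3))
  idx
}
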