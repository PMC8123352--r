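#' @name elastoflow-accessors
#' @title Accessors for elastoflow classes
#' @description Accessor generics for the S4 containers: material parameters,
#'   geometry-derived areas, frame and field extraction.
#' @param object an elastoflow S4 object.
#' @param i frame index.
#' @return The requested slot value or derived quantity.
NULL

#' @rdname elastoflow-accessors
#' @export
setGeneric("youngModulus", function(object) standardGeneric("youngModulus"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("poissonRatio", function(object) standardGeneric("poissonRatio"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("shearModulus", function(object) standardGeneric("shearModulus"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("contactArea", function(object) standardGeneric("contactArea"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("baseArea", function(object) standardGeneric("baseArea"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("modulusMap", function(object) standardGeneric("modulusMap"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("poissonMapOf", function(object) standardGeneric("poissonMapOf"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("shearWaveMap", function(object) standardGeneric("shearWaveMap"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("roiSummaries", function(object) standardGeneric("roiSummaries"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("performanceLog", function(object) standardGeneric("performanceLog"))
#' @rdname elastoflow-accessors
#' @export
setGeneric("framesUsed", function(object) standardGeneric("framesUsed"))

setMethod("youngModulus", "ElasticMaterial", function(object) object@youngModulus)
setMethod("poissonRatio", "ElasticMaterial", function(object) object@poissonRatio)
setMethod("shearModulus", "ElasticMaterial", function(object)
  object@youngModulus / (2 * (1 + object@poissonRatio)))

setMethod("pixelSize", "ScanGeometry", function(object) object@pixelSize)
setMethod("pixelSize", "CineSequence", function(object) object@pixelSize)
setMethod("contactArea", "ScanGeometry", function(object)
  object@transducerWidth * object@transducerDepth)
setMethod("baseArea", "ScanGeometry", function(object)
  object@baseWidth * object@baseDepth)

setMethod("frameTimes", "CineSequence", function(object) object@times)
setMethod("nFrames", "CineSequence", function(object) dim(object@frames)[3])
setMethod("getFrame", "CineSequence", function(object, i) object@frames[, , i])

setMethod("modulusMap", "ModulusResult", function(object) object@EMap)
setMethod("poissonMapOf", "ModulusResult", function(object) object@nuMap)
setMethod("shearWaveMap", "ModulusResult", function(object) object@ctMap)
setMethod("roiSummaries", "ModulusResult", function(object) object@roiSummaries)
setMethod("performanceLog", "ModulusResult", function(object) object@performance)
setMethod("framesUsed", "ModulusResult", function(object) object@framesUsed)

setMethod("show", "ElasticMaterial", function(object) {
  cat(sprintf("ElasticMaterial: E = %.4g kPa, nu = %.3f, gamma = %.3g, rho = %g kg/m^3\n",
              object@youngModulus / 1e3, object@poissonRatio, object@gamma,
              object@density))
})

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(paste0("ScanGeometry: footprint %.1f x %.1f mm, base %.1f x %.1f mm,\n",
                     "  height %.1f mm, pixel %.4g mm (A1 = %.0f mm^2, A2 = %.0f mm^2)\n"),
              object@transducerWidth * 1e3, object@transducerDepth * 1e3,
              object@baseWidth * 1e3, object@baseDepth * 1e3,
              object@specimenHeight * 1e3, object@pixelSize * 1e3,
              contactArea(object) * 1e6, baseArea(object) * 1e6))
})

setMethod("show", "CineSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CineSequence: %d frames of %d x %d px, %.4g mm/px, %.2f s span\n",
              d[3], d[1], d[2], object@pixelSize * 1e3, diff(range(object@times))))
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField %d -> %d (%s): %d x %d px, |u| up to %.2f px\n",
              object@referenceIndex, object@targetIndex,
              if (object@cumulative) "cumulative" else "incremental",
              nrow(object@ux), ncol(object@ux),
              max(sqrt(object@ux^2 + object@uz^2))))
})

setMethod("show", "StrainField", function(object) {
  cat(sprintf("StrainField (frames %d -> %d, M = %d): median ezz = %.4g over %d valid px\n",
              object@framePair[1], object@framePair[2], object@M,
              median(object@ezz[object@validMask]), sum(object@validMask)))
})

setMethod("show", "StressField", function(object) {
  cat(sprintf("StressField (%s): p = %.4g Pa, range %.4g .. %.4g Pa\n",
              object@assumption, object@pressure, min(object@sigmaZz),
              max(object@sigmaZz)))
})

setMethod("show", "ModulusResult", function(object) {
  ok <- is.finite(object@EMap)
  cat(sprintf("ModulusResult: %d x %d px map, %d/%d frames used\n",
              nrow(object@EMap), ncol(object@EMap), length(object@framesUsed),
              nrow(object@performance) + 1L))
  if (any(ok))
    cat(sprintf("  median E = %.4g kPa over %d valid px\n",
                median(object@EMap[ok]) / 1e3, sum(ok)))
  if (nrow(object@roiSummaries)) {
    cat("  ROI summaries:\n")
    print(object@roiSummaries, row.names = FALSE)
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, body E = %.4g kPa%s, %s stress model\n",
              object@imageSize[1], object@imageSize[2],
              youngModulus(object@bodyMaterial) / 1e3,
              if (object@inclusionRadius > 0)
                sprintf(", inclusion E = %.4g kPa (r = %.1f mm)",
                        youngModulus(object@inclusionMaterial) / 1e3,
                        object@inclusionRadius * 1e3) else "",
              object@stressModel))
})
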