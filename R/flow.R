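# Dense displacement tracking: preprocessing, frame correlation, the
# pluggable flow backends, warping, field composition, and sequence tracking
# with correlation-gated redefinition of the reference frame.

#' Gaussian preprocessing blur
#'
#' Dense flow estimators assume smooth image derivatives, so frames are
#' blurred before tracking. `sigma = 0` is the identity.
#'
#' @param img frame matrix.
#' @param sigma blur standard deviation in px (default 1).
#' @return Blurred matrix of the same shape.
#' @export
preprocessFrame <- function(img, sigma = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  cpp_gauss_blur(img, sigma)
}

#' 2D Pearson correlation of two frames
#'
#' \deqn{\rho = \frac{\sum_m\sum_n (A_{mn}-\bar A)(B_{mn}-\bar B)}
#'   {\sqrt{\sum (A_{mn}-\bar A)^2 \sum (B_{mn}-\bar B)^2}}}
#' evaluated over the pixels where both frames are defined (warped frames
#' carry NA outside the valid overlap).
#'
#' @param A,B frame matrices of equal shape.
#' @return Correlation in [-1, 1].
#' @export
frameCorrelation <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("frames must share the same shape")
  ok <- is.finite(A) & is.finite(B)
  if (sum(ok) < 2) stop("no valid overlap between frames")
  a <- A[ok] - mean(A[ok])
  b <- B[ok] - mean(B[ok])
  va <- sum(a^2); vb <- sum(b^2)
  if (va == 0 || vb == 0)
    stop("correlation undefined: zero-variance image")
  sum(a * b) / sqrt(va * vb)
}

#' Available dense-flow backends
#'
#' @return Character vector of registered backend names. `"lucaskanade"` is a
#'   pyramidal iterative Lucas-Kanade estimator, `"hornschunck"` a pyramidal
#'   Horn-Schunck variational estimator; both are implemented in compiled code.
#' @export
flowBackends <- function() c("lucaskanade", "hornschunck")

#' Estimate dense displacement between two frames
#'
#' Returns the per-pixel flow u such that `ref(x) ~ tgt(x + u(x))`: warping
#' the target by u maximises similarity to the reference.
#'
#' @param ref,tgt preprocessed frame matrices.
#' @param backend one of [flowBackends()].
#' @param referenceIndex,targetIndex frame indices recorded in the result.
#' @param ... tuning parameters passed to the backend (`maxLevels`, `nIter`,
#'   `sigmaWin`, `regFactor`, `sigmaFlow` for Lucas-Kanade; `maxLevels`,
#'   `nWarp`, `nRelax`, `alpha` for Horn-Schunck).
#' @return A [DisplacementField-class] (units: px).
#' @export
estimateFlow <- function(ref, tgt, backend = "lucaskanade",
                         referenceIndex = 1L, targetIndex = 2L, ...) {
  if (!all(dim(ref) == dim(tgt))) stop("frames must share the same shape")
  if (!backend %in% flowBackends())
    stop("unknown flow backend '", backend, "'; available: ",
         paste(flowBackends(), collapse = ", "))
  fl <- switch(backend,
               lucaskanade = cpp_flow_lk(ref, tgt, ...),
               hornschunck = cpp_flow_hs(ref, tgt, ...))
  displacementField(fl$ux, fl$uz, referenceIndex, targetIndex,
                    cumulative = FALSE)
}

#' Warp a frame by a displacement field
#'
#' Inverse mapping with bilinear interpolation: `out(x) = img(x + u(x))`.
#' Pixels sampling outside the image are NA and are excluded from
#' correlations.
#'
#' @param img frame matrix.
#' @param field a [DisplacementField-class] or `list(ux, uz)` in px.
#' @return Warped matrix with NA outside the valid domain.
#' @export
warpImage <- function(img, field) {
  u <- fieldComponents(field)
  cpp_warp_bilinear(img, u$ux, u$uz)
}

fieldComponents <- function(field) {
  if (is(field, "DisplacementField")) list(ux = field@ux, uz = field@uz)
  else field
}

#' Compose an accumulated field with a newly estimated field
#'
#' Proper warp composition `u_total(x) = u_acc(x) + u_new(x + u_acc(x))`:
#' the new field (expressed at the pixels of the redefined reference) is
#' sampled at the positions where the accumulated field lands. Naive
#' pixelwise addition (`method = "add"`) is provided as a debug mode only;
#' it is wrong for large motion.
#'
#' @param acc accumulated [DisplacementField-class] (frame 1 -> frame r).
#' @param new newly estimated field (frame r -> frame k), same shape.
#' @param method "warp" (default) or "add".
#' @return Cumulative [DisplacementField-class] frame 1 -> frame k.
#' @export
composeFields <- function(acc, new, method = c("warp", "add")) {
  method <- match.arg(method)
  if (method == "add") {
    return(displacementField(acc@ux + new@ux, acc@uz + new@uz,
                             acc@referenceIndex, new@targetIndex,
                             cumulative = TRUE))
  }
  sx <- cpp_warp_bilinear(new@ux, acc@ux, acc@uz)
  sz <- cpp_warp_bilinear(new@uz, acc@ux, acc@uz)
  # landing outside the redefined reference: fall back to the local value so
  # the field stays finite (border pixels only)
  na <- !is.finite(sx) | !is.finite(sz)
  sx[na] <- new@ux[na]
  sz[na] <- new@uz[na]
  displacementField(acc@ux + sx, acc@uz + sz, acc@referenceIndex,
                    new@targetIndex, cumulative = TRUE)
}

#' Track a CINE sequence against an automatically redefined reference
#'
#' Estimates the dense displacement from the current reference frame to every
#' subsequent frame. After each estimate the target is warped back and the 2D
#' correlation rho with the reference is computed over the valid overlap; when
#' rho drops below `rhoMin` the current frame becomes the new reference and
#' the displacement accumulated so far is composed with all further fields,
#' so every returned field is cumulative (frame 1 -> frame k). If tracking
#' between directly consecutive frames falls below `min(rhoMin, abortFloor)`
#' the sequence is untrackable and an error is raised.
#'
#' @param cine a [CineSequence-class] (raw frames; blurred internally).
#' @param rhoMin correlation threshold for reference redefinition
#'   (default 0.9).
#' @param backend flow backend name, see [flowBackends()].
#' @param blurSigma preprocessing blur in px (default 1).
#' @param compose "warp" (default) or "add" (debug).
#' @param abortFloor hard correlation floor for consecutive-frame tracking
#'   (default 0.5).
#' @param ... passed to [estimateFlow()].
#' @return `list(fields = <list of cumulative DisplacementField>,`
#'   `log = data.frame(frame, rho, switched), backend = <name>)`; `fields[[k]]`
#'   maps frame k+1 back to the frame-1 configuration.
#' @export
trackSequence <- function(cine, rhoMin = 0.9, backend = "lucaskanade",
                          blurSigma = 1, compose = c("warp", "add"),
                          abortFloor = 0.5, ...) {
  compose <- match.arg(compose)
  n <- nFrames(cine)
  imgs <- lapply(seq_len(n), function(k)
    preprocessFrame(getFrame(cine, k), blurSigma))
  fields <- vector("list", n - 1)
  log <- data.frame(frame = integer(), rho = numeric(), switched = logical())
  refIdx <- 1L
  acc <- NULL # cumulative field frame 1 -> refIdx
  for (k in 2:n) {
    v <- estimateFlow(imgs[[refIdx]], imgs[[k]], backend = backend,
                      referenceIndex = refIdx, targetIndex = k, ...)
    rho <- frameCorrelation(imgs[[refIdx]], warpImage(imgs[[k]], v))
    cum <- if (is.null(acc))
      displacementField(v@ux, v@uz, 1L, k, cumulative = TRUE)
    else composeFields(acc, v, method = compose)
    fields[[k - 1]] <- cum
    switched <- FALSE
    if (rho < rhoMin) {
      if (refIdx == k - 1L && rho < min(rhoMin, abortFloor))
        stop("untrackable sequence: correlation ", signif(rho, 3),
             " between consecutive frames ", refIdx, " and ", k)
      refIdx <- k
      acc <- cum
      switched <- TRUE
    }
    log <- rbind(log, data.frame(frame = k, rho = rho, switched = switched))
  }
  list(fields = fields, log = log, backend = backend)
}

#' Incremental displacement between two cumulative fields
#'
#' Both cumulative fields are sampled at frame-1 pixels, so their difference
#' is the frame-to-frame motion expressed on the common reference grid.
#'
#' @param prev,curr cumulative [DisplacementField-class] objects.
#' @return Incremental [DisplacementField-class].
#' @export
incrementalField <- function(prev, curr) {
  displacementField(curr@ux - prev@ux, curr@uz - prev@uz,
                    prev@targetIndex, curr@targetIndex, cumulative = FALSE)
}
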