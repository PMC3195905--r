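#' Accessors for lctrw S4 objects
#'
#' Small accessor generics: slot access from user code should go through
#' these rather than `@`.
#'
#' @param object an lctrw S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("generatorBase", function(object) standardGeneric("generatorBase"))
#' @rdname accessors
#' @export
setGeneric("spaceDim", function(object) standardGeneric("spaceDim"))
#' @rdname accessors
#' @export
setGeneric("allowedCells", function(object) standardGeneric("allowedCells"))
#' @rdname accessors
#' @export
setGeneric("stageDepth", function(object) standardGeneric("stageDepth"))
#' @rdname accessors
#' @export
setGeneric("sideLength", function(object) standardGeneric("sideLength"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("walkKind", function(object) standardGeneric("walkKind"))
#' @rdname accessors
#' @export
setGeneric("msdValues", function(object) standardGeneric("msdValues"))
#' @rdname accessors
#' @export
setGeneric("msdTimes", function(object) standardGeneric("msdTimes"))
#' @rdname accessors
#' @export
setGeneric("scalingExponent", function(object) standardGeneric("scalingExponent"))
#' @rdname accessors
#' @export
setGeneric("scalingPrefactor", function(object) standardGeneric("scalingPrefactor"))

setMethod("generatorBase", "GeneratorMask", function(object) object@nu)
setMethod("generatorBase", "FractalSupport",
          function(object) object@generator@nu)
setMethod("spaceDim", "GeneratorMask", function(object) object@dim)
setMethod("spaceDim", "FractalSupport", function(object) object@generator@dim)
setMethod("spaceDim", "Trajectory", function(object) ncol(object@positions))
setMethod("allowedCells", "GeneratorMask", function(object) sum(object@allowed))
setMethod("allowedCells", "FractalSupport",
          function(object) sum(object@generator@allowed))
setMethod("stageDepth", "FractalSupport", function(object) object@kmax)
setMethod("sideLength", "FractalSupport",
          function(object) object@generator@nu^object@kmax)
setMethod("eventTimes", "Trajectory", function(object) object@times)
setMethod("positions", "Trajectory", function(object) object@positions)
setMethod("walkKind", "Trajectory", function(object) object@kind)
setMethod("msdValues", "MSDCurve", function(object) object@values)
setMethod("msdTimes", "MSDCurve", function(object) object@times)
setMethod("scalingExponent", "ScalingFit", function(object) object@exponent)
setMethod("scalingPrefactor", "ScalingFit", function(object) object@prefactor)
setMethod("scalingExponent", "SubpopResult", function(object) object@gsub)

setMethod("show", "GeneratorMask", function(object) {
  cat(sprintf("GeneratorMask: nu = %d, dim = %d, %d/%d cells allowed\n",
              object@nu, object@dim, sum(object@allowed),
              object@nu^object@dim))
})

setMethod("show", "FractalSupport", function(object) {
  cat(sprintf(
    "FractalSupport (GSC): nu = %d, dim = %d, stage kmax = %d, side = %d\n",
    object@generator@nu, object@generator@dim, object@kmax,
    object@generator@nu^object@kmax))
  cat(sprintf("  generator: %d/%d cells allowed\n",
              sum(object@generator@allowed),
              object@generator@nu^object@generator@dim))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory [%s]: %d events, dim = %d, duration = %.6g, gamma = %g\n",
    object@kind, length(object@times), ncol(object@positions),
    max(object@times), object@gamma))
  if (is.finite(object@rmax))
    cat(sprintf("  geometric cap: r_max = %g ell0\n", object@rmax))
  if (!is.null(object@support))
    cat(sprintf("  on GSC support nu = %d, kmax = %d\n",
                generatorBase(object@support), object@support@kmax))
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve [%s average]: %d points, %d track(s)\n",
              object@averaging, length(object@times), object@nTracks))
})

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf(
    "ScalingFit: MSD(t) = %.4g * t^%.4f  (window [%.3g, %.3g], R^2 = %.4f)\n",
    object@prefactor, object@exponent, object@window[1], object@window[2],
    object@r2))
})

setMethod("show", "SubpopResult", function(object) {
  cat(sprintf(
    "SubpopResult: gsub = %.4f (csub = %.4f), |gtilde - gsub| = %.3g\n",
    object@gsub, object@csub, object@variation))
  cat(sprintf("  l_max* = %d, bounds [%.4f, %.4f]\n",
              object@lmaxOpt, object@bounds[1], object@bounds[2]))
})

setMethod("show", "FCSParams", function(object) {
  cat(sprintf(
    "FCSParams: N = %.4g, tauD = %.4g s, gamma = %.3f, s = %.3g, dim = %d, m = %d\n",
    object@N, object@tauD, object@gamma, object@s, object@dim, object@m))
})

setMethod("show", "ExposureModel", function(object) {
  mom <- exposureMoments(object)
  cat(sprintf("ExposureModel: rmax = %.4g m, q = %g\n", object@rmax, object@q))
  cat(sprintf("  rbar = %.4g m, sigma_r^2 = %.4g m^2, MSD cap = %.4g m^2\n",
              mom$rbar, mom$sigma2, mom$msdCap))
})

setMethod("show", "WaitingTimeModel", function(object) {
  cat(sprintf(
    "WaitingTimeModel: inverse-gamma, gamma = %.3f, scale = %g (heavy tail ~ t^-%.3f)\n",
    object@gamma, object@scale, object@gamma))
})

setMethod("show", "CountingConfig", function(object) {
  s <- countingSummary(object)
  cat(sprintf("CountingConfig: cm = %.3g M, dV = %.3g L, tauD = %.3g s, T = %.3g s\n",
              object@cm, object@dV, object@tauD, object@T))
  cat(sprintf("  C = %.4g, N = P(1) = %.4g, cutoff = %.4g M, Tm = %.4g s, N_lmax = %.4g\n",
              s$C, s$N, s$cutoff, s$Tm, s$NlmaxReal))
})
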