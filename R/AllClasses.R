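#' @import methods
NULL

#' Generator mask for a generalized Sierpinski carpet
#'
#' A boolean grid of `nu^dim` cells that defines one renormalization stage of
#' a generalized Sierpinski carpet (GSC). `TRUE` cells are accessible. The
#' GSC construction restricts deletion to at most half of the cells.
#'
#' @slot nu integer base of the carpet (side length of the generator).
#' @slot dim spatial dimension, 2 or 3.
#' @slot allowed logical array of dimension `rep(nu, dim)`; `allowed[x+1,
#'   y+1(, z+1)]` refers to the 0-based generator cell `(x, y, z)`.
#'
#' @seealso [generatorMask()], [fractalSupport()]
#' @export
setClass("GeneratorMask",
  representation(nu = "integer", dim = "integer", allowed = "array"))

setValidity("GeneratorMask", function(object) {
  msgs <- character()
  if (length(object@nu) != 1L || object@nu < 2L)
    msgs <- c(msgs, "nu must be a single integer >= 2")
  if (!object@dim %in% c(2L, 3L))
    msgs <- c(msgs, "dim must be 2 or 3")
  if (!is.logical(object@allowed) ||
      !identical(dim(object@allowed), rep(object@nu, object@dim)))
    msgs <- c(msgs, "allowed must be a logical array of dim rep(nu, dim)")
  else {
    n_cells <- object@nu^object@dim
    n_allowed <- sum(object@allowed)
    if (n_allowed < 1L)
      msgs <- c(msgs, "at least one generator cell must be allowed")
    if (n_cells - n_allowed > n_cells / 2)
      msgs <- c(msgs, "a GSC generator may delete at most half of its cells")
  }
  if (length(msgs)) msgs else TRUE
})

#' Generalized Sierpinski carpet support
#'
#' A fractal lattice support obtained by iterating a [GeneratorMask-class]
#' `kmax` times. The support is virtual: accessibility of a site is decided
#' on demand by stage-wise coarse graining (renormalization), never by
#' materializing the lattice.
#'
#' @slot generator a [GeneratorMask-class].
#' @slot kmax integer iteration depth (>= 1); the bounding box has side
#'   `nu^kmax` lattice units.
#'
#' @seealso [fractalSupport()], [isAccessible()]
#' @export
setClass("FractalSupport",
  representation(generator = "GeneratorMask", kmax = "integer"))

setValidity("FractalSupport", function(object) {
  if (length(object@kmax) != 1L || is.na(object@kmax) || object@kmax < 1L)
    return("kmax must be a single integer >= 1")
  TRUE
})

setClassUnion("FractalSupportOrNULL", c("FractalSupport", "NULL"))

#' Single-molecule lattice trajectory
#'
#' Timestamped lattice positions of one simulated molecule. For Brownian and
#' blind-ant walks the event times are the uniform tick times 0, 1, 2, ...;
#' for CTRW/LCTRW they are the cumulative waiting times. Between events the
#' molecule sits on the last visited site (right-continuous step function).
#'
#' @slot times numeric event times, strictly increasing, `times[1] == 0`.
#' @slot positions integer matrix with one row per event and one column per
#'   coordinate; consecutive rows differ by one unit step in one coordinate
#'   or are equal (a blocked blind-ant attempt).
#' @slot kind one of `"brownian"`, `"rwf"`, `"ctrw"`, `"lctrw"`.
#' @slot gamma waiting-time exponent used (1 for non-CTRW kinds).
#' @slot support the [FractalSupport-class] walked on, or `NULL` for the full
#'   lattice.
#' @slot seed integer seed used, or `NA`.
#' @slot ell0 lattice step length (length units, default 1).
#' @slot rmax geometric displacement cap in `ell0` units (`Inf` if none).
#' @slot meta free-form list (e.g. the occupancy `C` of an LCTRW run).
#'
#' @export
setClass("Trajectory",
  representation(times = "numeric", positions = "matrix", kind = "character",
                 gamma = "numeric", support = "FractalSupportOrNULL",
                 seed = "integer", ell0 = "numeric", rmax = "numeric",
                 meta = "list"),
  prototype(gamma = 1, support = NULL, seed = NA_integer_, ell0 = 1,
            rmax = Inf, meta = list()))

setValidity("Trajectory", function(object) {
  msgs <- character()
  n <- length(object@times)
  if (n < 1L || object@times[1] != 0)
    msgs <- c(msgs, "times must start at 0")
  if (n > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (nrow(object@positions) != n)
    msgs <- c(msgs, "positions must have one row per event")
  if (!object@kind %in% c("brownian", "rwf", "ctrw", "lctrw"))
    msgs <- c(msgs, "kind must be brownian, rwf, ctrw or lctrw")
  if (n > 1L) {
    d <- abs(diff(object@positions))
    if (any(rowSums(d) > 1L))
      msgs <- c(msgs, "consecutive positions must differ by at most one unit step")
  }
  if (length(msgs)) msgs else TRUE
})

#' Mean square displacement curve
#'
#' MSD values against lag times (temporal average) or absolute times
#' (ensemble / sub-ensemble average), in units of `ell0^2`.
#'
#' @slot times abscissa (lags for `"time"` averaging, times otherwise).
#' @slot values MSD values, non-negative.
#' @slot averaging one of `"time"`, `"ensemble"`, `"sub_ensemble"`.
#' @slot nTracks number of trajectories averaged.
#' @slot T measurement time (NA when not applicable).
#'
#' @export
setClass("MSDCurve",
  representation(times = "numeric", values = "numeric",
                 averaging = "character", nTracks = "integer", T = "numeric"),
  prototype(nTracks = 1L, T = NA_real_))

setValidity("MSDCurve", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (any(!is.finite(object@values)) || any(object@values < -1e-12))
    msgs <- c(msgs, "MSD values must be finite and non-negative")
  if (!object@averaging %in% c("time", "ensemble", "sub_ensemble"))
    msgs <- c(msgs, "averaging must be time, ensemble or sub_ensemble")
  if (length(msgs)) msgs else TRUE
})

#' Power-law scaling fit of an MSD curve
#'
#' Result of an ordinary least squares fit of `log(MSD)` on `log(t)`:
#' `MSD(t) = prefactor * t^exponent` over the fit window.
#'
#' @slot exponent fitted anomalous scaling exponent (slope in log-log).
#' @slot prefactor fitted amplitude (exp of the intercept), `ell0^2 /
#'   time^exponent` units.
#' @slot window numeric length-2 fit window `[t_lo, t_hi]`.
#' @slot r2 coefficient of determination in log-log space.
#'
#' @export
setClass("ScalingFit",
  representation(exponent = "numeric", prefactor = "numeric",
                 window = "numeric", r2 = "numeric"))

#' Family of ideal power-law single-molecule MSD tracks
#'
#' `lmax` ideal curves `f_l(t) = A(g_l) t^{g_l}` with exponents ordered as
#' `g_l = gmin + l (gmax - gmin) / lmax`, `l = 1..lmax`, on a common time
#' grid. Used by the subpopulation-averaging minimization.
#'
#' @slot gmin,gmax exponent bounds, `0 < gmin < gmax < 1`.
#' @slot lmax number of tracks.
#' @slot grid measurement time grid (positive, increasing).
#' @slot exponents the `g_l` values.
#' @slot prefactors the `A(g_l)` values.
#' @slot curves matrix `lmax x length(grid)` of curve values.
#' @slot prefactorRule `"gamma"` (A = Gamma(g_l)) or `"unit"` (A = 1).
#'
#' @export
setClass("TrackFamily",
  representation(gmin = "numeric", gmax = "numeric", lmax = "integer",
                 grid = "numeric", exponents = "numeric",
                 prefactors = "numeric", curves = "matrix",
                 prefactorRule = "character"))

setValidity("TrackFamily", function(object) {
  msgs <- character()
  if (!(object@gmin > 0 && object@gmin < object@gmax && object@gmax < 1))
    msgs <- c(msgs, "need 0 < gmin < gmax < 1")
  if (object@lmax < 1L) msgs <- c(msgs, "lmax must be >= 1")
  if (any(object@grid <= 0) || is.unsorted(object@grid, strictly = TRUE))
    msgs <- c(msgs, "grid must be positive and strictly increasing")
  if (any(object@curves <= 0)) msgs <- c(msgs, "curves must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Result of the subpopulation bound optimization
#'
#' @slot gsub fitted subpopulation scaling exponent.
#' @slot csub fitted log-prefactor.
#' @slot variation achieved `|gtilde - gsub|`.
#' @slot lmaxOpt optimal number of tracks in the subpopulation.
#' @slot bounds numeric length-2 optimal `(gmin, gmax)`.
#'
#' @export
setClass("SubpopResult",
  representation(gsub = "numeric", csub = "numeric", variation = "numeric",
                 lmaxOpt = "integer", bounds = "numeric"))

setValidity("SubpopResult", function(object) {
  if (object@lmaxOpt < 1L) return("lmaxOpt must be >= 1")
  if (object@gsub < object@bounds[1] - 1e-9 ||
      object@gsub > object@bounds[2] + 1e-9)
    return("gsub must lie within the bounds")
  TRUE
})

#' Anomalous-diffusion FCS model parameters
#'
#' Parameter bundle for the normalized auto/cross-correlation of anomalous
#' diffusion through a 3D Gaussian (or 2D) observation volume.
#'
#' @slot N mean molecule number in the observation volume (may be < 1: the
#'   Poisson single-molecule probability).
#' @slot tauD diffusion time (s).
#' @slot gamma anomaly exponent in (0, 1.5].
#' @slot s structural factor `z0 / omega` (axial over radial extent).
#' @slot dim 2 (membrane) or 3.
#' @slot m photon order of the excitation (1 or 2).
#' @slot omega radial waist of the volume (m, NA if unused).
#' @slot z0 axial half-length (m, NA if unused).
#'
#' @export
setClass("FCSParams",
  representation(N = "numeric", tauD = "numeric", gamma = "numeric",
                 s = "numeric", dim = "integer", m = "integer",
                 omega = "numeric", z0 = "numeric"),
  prototype(gamma = 1, s = 5, dim = 3L, m = 1L,
            omega = NA_real_, z0 = NA_real_))

setValidity("FCSParams", function(object) {
  msgs <- character()
  if (object@N <= 0) msgs <- c(msgs, "N must be positive")
  if (object@tauD <= 0) msgs <- c(msgs, "tauD must be positive")
  if (object@gamma <= 0) msgs <- c(msgs, "gamma must be positive")
  if (object@s <= 0) msgs <- c(msgs, "s must be positive")
  if (!object@dim %in% c(2L, 3L)) msgs <- c(msgs, "dim must be 2 or 3")
  if (!object@m %in% c(1L, 2L)) msgs <- c(msgs, "m must be 1 or 2")
  if (is.finite(object@omega) && is.finite(object@z0) &&
      abs(object@s - object@z0 / object@omega) > 1e-8 * object@s)
    msgs <- c(msgs, "s must equal z0/omega when both geometry fields are set")
  if (length(msgs)) msgs else TRUE
})

#' Single-molecule counting configuration
#'
#' @slot cm molar bulk concentration (mol/L).
#' @slot dV observation volume (L).
#' @slot tauD diffusion time (s).
#' @slot T measurement time (s).
#'
#' @export
setClass("CountingConfig",
  representation(cm = "numeric", dV = "numeric", tauD = "numeric",
                 T = "numeric"))

setValidity("CountingConfig", function(object) {
  vals <- c(object@cm, object@dV, object@tauD, object@T)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("cm, dV, tauD and T must all be positive and finite")
  TRUE
})

#' Weibull exposure model
#'
#' Frequency distribution of cumulative exposure to interaction sites:
#' `m(<r)/m_total = 1 - exp(-(r/rmax)^q)`, with the small-`r` power law
#' `(r/rmax)^q` and its moments on `[0, rmax]`.
#'
#' @slot rmax maximum linear size (m), the geometric size of the cell or its
#'   nucleus.
#' @slot q positive shape parameter (a positive integer in the model's
#'   derivation; positive reals are accepted).
#'
#' @export
setClass("ExposureModel", representation(rmax = "numeric", q = "numeric"))

setValidity("ExposureModel", function(object) {
  if (object@rmax <= 0) return("rmax must be positive")
  if (object@q <= 0) return("q must be positive")
  TRUE
})

#' Heavy-tailed waiting time model
#'
#' Inverse-gamma waiting time law with density
#' `psi(t) = exp(-1/t) t^(-(1+gamma)) / Gamma(gamma)` (scale 1), whose first
#' moment is infinite for `gamma <= 1`; draws are scaled by `scale`.
#'
#' @slot gamma temporal heterogeneity exponent in (0, 1].
#' @slot scale time-unit scale factor (> 0, default 1).
#'
#' @export
setClass("WaitingTimeModel",
  representation(gamma = "numeric", scale = "numeric"),
  prototype(scale = 1))

setValidity("WaitingTimeModel", function(object) {
  if (object@gamma <= 0 || object@gamma > 1)
    return("gamma must lie in (0, 1]")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})
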