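#' Construct a Weibull exposure model
#'
#' Frequency distribution of cumulative molecular exposure to interaction
#' sites, with maximum linear size `rmax` set by the geometry of the cell or
#' its nucleus, and shape `q`.
#'
#' @param rmax maximum linear size (m).
#' @param q positive shape parameter.
#' @return an [ExposureModel-class].
#' @examples
#' exposureModel(rmax = 22.8e-6, q = 2)
#' @export
exposureModel <- function(rmax, q) {
  new("ExposureModel", rmax = as.numeric(rmax), q = as.numeric(q))
}

#' Cumulative exposure fraction
#'
#' `m(<r)/m_total = 1 - exp(-(r/rmax)^q)`; the complement
#' `m(>r)/m_total = exp(-(r/rmax)^q)` is returned by
#' [weibullComplement()]. For small `r` the cumulative fraction reduces to
#' the power law `(r/rmax)^q` (first-order McLaurin truncation).
#'
#' @param r size (m, >= 0).
#' @param model an [ExposureModel-class].
#' @return fraction in [0, 1).
#' @export
weibullCumulative <- function(r, model) {
  stopifnot(is(model, "ExposureModel"))
  if (any(r < 0)) stop("r must be non-negative")
  1 - exp(-(r / model@rmax)^model@q)
}

#' @rdname weibullCumulative
#' @export
weibullComplement <- function(r, model) 1 - weibullCumulative(r, model)

#' Exposure probability densities
#'
#' The Weibull density `f(r) = q r^(q-1) / rmax^q * exp(-(r/rmax)^q)` on
#' `[0, Inf)` and its small-`r` power-law reduction
#' `f(r) = q r^(q-1) / rmax^q` supported on `[0, rmax]` (zero beyond).
#'
#' @inheritParams weibullCumulative
#' @return list with numeric vectors `weibull` and `powerLaw`.
#' @export
exposureDensities <- function(r, model) {
  stopifnot(is(model, "ExposureModel"))
  if (any(r < 0)) stop("r must be non-negative")
  q <- model@q; rmax <- model@rmax
  base <- q * r^(q - 1) / rmax^q
  list(weibull = base * exp(-(r / rmax)^q),
       powerLaw = ifelse(r <= rmax, base, 0))
}

#' Moments of the power-law exposure distribution
#'
#' First and second central moments of the power-law density on
#' `[0, rmax]`: mean interaction size `rbar = q/(q+1) * rmax`, variance
#' `sigma_r^2 = q / ((q+2)(q+1)^2) * rmax^2`, and the MSD cap
#' `msdCap = rbar^2` -- the upper limiting value of the mean square
#' displacement used as the geometric limit of an LCTRW.
#'
#' @param model an [ExposureModel-class].
#' @return list with `rbar` (m), `sigma2` (m^2) and `msdCap` (m^2).
#' @examples
#' exposureMoments(exposureModel(22.8e-6, 2))  # rbar = 15.2 um
#' @export
exposureMoments <- function(model) {
  stopifnot(is(model, "ExposureModel"))
  q <- model@q; rmax <- model@rmax
  rbar <- q / (q + 1) * rmax
  list(rbar = rbar,
       sigma2 = q / ((q + 2) * (q + 1)^2) * rmax^2,
       msdCap = rbar^2)
}

#' Linear size from a volume
#'
#' Molecules and compartments of irregular shape are assigned the linear
#' dimension `volume^(1/3)` (unit proportionality constant).
#'
#' @param volume volume (> 0).
#' @return linear size.
#' @export
sizeFromVolume <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  volume^(1 / 3)
}

#' Geometric cap radius for an LCTRW, in lattice units
#'
#' The LCTRW displacement cap defaults to the mean interaction size `rbar`
#' (so the attainable MSD equals the model's `msdCap = rbar^2`), expressed
#' in walker length units by dividing by the physical step length `ell0`.
#'
#' @param model an [ExposureModel-class].
#' @param ell0 physical length of one lattice step (m).
#' @return cap radius in lattice units.
#' @export
capRadius <- function(model, ell0 = 1) {
  if (ell0 <= 0) stop("ell0 must be positive")
  exposureMoments(model)$rbar / ell0
}
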