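#' Construct FCS model parameters
#'
#' @param N mean molecule number in the observation volume (> 0; values
#'   below 1 are the single-molecule regime).
#' @param tauD diffusion time (s).
#' @param gamma anomaly exponent (1 = normal diffusion).
#' @param s structural factor `z0/omega`; computed from the geometry when
#'   `omega` and `z0` are given.
#' @param dim 2 or 3.
#' @param m photon order (1 or 2).
#' @param omega,z0 optional radial waist and axial half-length (m).
#' @return an [FCSParams-class].
#' @export
fcsParams <- function(N, tauD, gamma = 1, s = 5, dim = 3L, m = 1L,
                      omega = NA_real_, z0 = NA_real_) {
  if (is.finite(omega) && is.finite(z0)) s <- z0 / omega
  new("FCSParams", N = as.numeric(N), tauD = as.numeric(tauD),
      gamma = as.numeric(gamma), s = as.numeric(s), dim = as.integer(dim),
      m = as.integer(m), omega = as.numeric(omega), z0 = as.numeric(z0))
}

#' Anomalous-diffusion FCS correlation model
#'
#' Normalized auto- (and two-color cross-) correlation of anomalous
#' diffusion through a Gaussian observation volume:
#' `G(tau) = (1/N) [1 + (tau/tauD)^g]^-1 [1 + (1/s^2)(tau/tauD)^g]^-(dim-2)/2 + 1`.
#' At zero lag `G - 1 = 1/N`; for `dim = 2` the axial factor drops; for
#' `g = 1`, `dim = 3` the classical single-component FCS form is recovered.
#'
#' @param tau lag times (s, >= 0).
#' @param params an [FCSParams-class].
#' @return numeric vector of correlation values.
#' @export
correlationModel <- function(tau, params) {
  stopifnot(is(params, "FCSParams"), all(tau >= 0))
  u <- (tau / params@tauD)^params@gamma
  ax <- if (params@dim == 3L) (1 + u / params@s^2)^(-0.5) else 1
  1 / params@N * (1 + u)^(-1) * ax + 1
}

#' Apparent diffusion coefficient of anomalous motion
#'
#' `D_app(t) = prefactor / (2 dim) * t^(gamma - 1)`, defined so that
#' `MSD(t) = 2 dim D_app(t) t = prefactor * t^gamma` holds identically.
#'
#' @param t time (> 0).
#' @param gamma anomaly exponent.
#' @param prefactor MSD amplitude (length^2 per fractional time).
#' @param dim 2 or 3.
#' @return numeric vector.
#' @export
dApp <- function(t, gamma, prefactor, dim = 3L) {
  stopifnot(all(t > 0))
  prefactor / (2 * dim) * t^(gamma - 1)
}

#' Instantaneous diffusion coefficient
#'
#' `D_inst(t) = (1 / (2 dim)) d<r^2>/dt = gamma * D_app(t)`, i.e. the local
#' slope of the MSD; `D_app = D_inst / gamma`.
#'
#' @inheritParams dApp
#' @return numeric vector.
#' @export
dInst <- function(t, gamma, prefactor, dim = 3L) {
  gamma * dApp(t, gamma, prefactor, dim)
}

#' Anomalous diffusion time of the observation volume
#'
#' Closed form of the fixed point `tau = omega^2 / (4 m D_app(tau))`:
#' `tauD = [omega^2 * 2 dim / (4 m prefactor)]^(1/gamma)`. For `gamma = 1`,
#' `dim = 3`, `m = 1` and `prefactor = 6 D` this reduces to the classical
#' `omega^2 / (4 D)`; two-photon excitation (`m = 2`) halves it.
#'
#' @param omega radial waist of the observation volume (m).
#' @param m photon order (1 or 2).
#' @param prefactor MSD amplitude.
#' @param gamma anomaly exponent (> 0).
#' @param dim 2 or 3.
#' @return diffusion time (same time units as the prefactor's).
#' @export
diffusionTime <- function(omega, m = 1L, prefactor, gamma = 1, dim = 3L) {
  stopifnot(omega > 0, m %in% c(1L, 2L), prefactor > 0, dim %in% c(2L, 3L))
  if (gamma <= 0) stop("gamma must be positive")
  tauD <- (omega^2 * 2 * dim / (4 * m * prefactor))^(1 / gamma)
  # self-consistency of the fixed-point reading
  resid <- abs(tauD - omega^2 / (4 * m * dApp(tauD, gamma, prefactor, dim)))
  if (resid > 1e-8 * tauD)
    warning("fixed-point identity violated beyond tolerance")
  tauD
}

#' Fit the FCS correlation model to a measured curve
#'
#' Nonlinear least squares for `(N, tauD, gamma)` with the geometry (`s`,
#' `dim`) held fixed. `N` and `tauD` are fitted in log-space to enforce
#' positivity; `gamma` is bounded to `(0.05, 1.5]` so boundary solutions of
#' subdiffusive data are still detectable. Delegates the optimization to
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param tau lag times (s), at least 10 points spanning the decay.
#' @param G measured correlation values.
#' @param dim 2 or 3.
#' @param s structural factor (fixed).
#' @param start optional named list `list(N=, tauD=, gamma=)` of starting
#'   values; a heuristic start is derived from the curve otherwise.
#' @param fixGamma optional value to hold `gamma` fixed (e.g. 1 to force
#'   the normal-diffusion model).
#' @return list with `params` ([FCSParams-class]), `residuals`, `rss`,
#'   `cov` (parameter covariance on the internal scale, NA on failure) and
#'   `converged`.
#' @export
fitCorrelation <- function(tau, G, dim = 3L, s = 5, start = NULL,
                           fixGamma = NULL) {
  stopifnot(length(tau) == length(G), length(tau) >= 10, all(tau > 0))
  amp <- max(G) - 1
  if (amp <= 0) stop("curve has no positive amplitude above the baseline")
  if (is.null(start)) {
    N0 <- 1 / amp
    half <- 1 + amp / 2
    tauD0 <- tau[which.min(abs(G - half))]
    start <- list(N = N0, tauD = max(tauD0, min(tau)), gamma = 0.9)
  }
  dat <- data.frame(tau = tau, G = G)
  model <- function(lN, ltauD, g, tau) {
    u <- (tau / exp(ltauD))^g
    ax <- if (dim == 3L) (1 + u / s^2)^(-0.5) else 1
    exp(-lN) * (1 + u)^(-1) * ax + 1
  }
  if (is.null(fixGamma)) {
    fit <- try(minpack.lm::nlsLM(
      G ~ model(lN, ltauD, g, tau), data = dat,
      start = list(lN = log(start$N), ltauD = log(start$tauD),
                   g = start$gamma),
      lower = c(-Inf, -Inf, 0.05), upper = c(Inf, Inf, 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    g <- fixGamma
    fit <- try(minpack.lm::nlsLM(
      G ~ model(lN, ltauD, g, tau), data = dat,
      start = list(lN = log(start$N), ltauD = log(start$tauD)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(list(params = fcsParams(start$N, start$tauD,
                                   if (is.null(fixGamma)) start$gamma
                                   else fixGamma, s = s, dim = dim),
                residuals = NA, rss = NA_real_, cov = NA,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  gHat <- if (is.null(fixGamma)) unname(cf["g"]) else fixGamma
  params <- fcsParams(exp(unname(cf["lN"])), exp(unname(cf["ltauD"])),
                      gHat, s = s, dim = dim)
  vc <- try(stats::vcov(fit), silent = TRUE)
  list(params = params, residuals = stats::residuals(fit),
       rss = sum(stats::residuals(fit)^2),
       cov = if (inherits(vc, "try-error")) NA else vc,
       converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
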