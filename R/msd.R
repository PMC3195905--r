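#' Logarithmically spaced grid
#'
#' `round(pointsPerDecade * log10(b/a)) + 1` points spaced evenly in
#' `log10` between `a` and `b`, endpoints included.
#'
#' @param a,b grid limits, `0 < a < b`.
#' @param pointsPerDecade grid density (default 25).
#' @return numeric vector.
#' @export
logSpacedGrid <- function(a, b, pointsPerDecade = 25) {
  stopifnot(a > 0, b > a)
  n <- max(2L, as.integer(round(pointsPerDecade * log10(b / a))) + 1L)
  10^seq(log10(a), log10(b), length.out = n)
}

# Piecewise-constant position lookup: row indices of P for query times.
.posIndex <- function(times, queries) findInterval(queries, times)

# Simulated horizon of a trajectory: the nominal total time T for CTRW-style
# walks (the molecule is still waiting on its site at T), else the last event.
.horizon <- function(traj) {
  if (!is.null(traj@meta$T)) traj@meta$T else max(traj@times)
}

.squaredDisp <- function(P, i, j) {
  d <- P[j, , drop = FALSE] - P[i, , drop = FALSE]
  rowSums(d * d)
}

#' Time-averaged MSD of a single trajectory
#'
#' For each lag `Delta`, the temporal average
#' `(1/(T - Delta)) * integral_0^(T-Delta) |r(t + Delta) - r(t)|^2 dt`
#' with the trajectory interpreted as a right-continuous step function
#' between events (the molecule waits on its site). The integral is computed
#' exactly over the piecewise-constant partition, so the estimator is free
#' of time-discretization error.
#'
#' @param traj a [Trajectory-class].
#' @param lags positive lags, all `< T`; default: 25-per-decade log grid
#'   from the first event spacing up to `T / 10`.
#' @param T measurement time (default: trajectory duration). Must not
#'   exceed the simulated horizon.
#' @return an [MSDCurve-class] with `averaging = "time"`, in `ell0^2` units.
#' @export
timeAveragedMSD <- function(traj, lags = NULL, T = NULL) {
  stopifnot(is(traj, "Trajectory"))
  tt <- traj@times
  if (is.null(T)) T <- .horizon(traj)
  if (T > .horizon(traj) + 1e-9) stop("T exceeds the trajectory duration")
  if (is.null(lags)) {
    lo <- if (length(tt) > 1) max(min(diff(tt)), T * 1e-6) else T / 100
    lags <- logSpacedGrid(lo, T / 10, 25)
  }
  if (any(lags >= T)) stop("all lags must be smaller than T")
  if (any(lags <= 0)) stop("lags must be positive")
  P <- traj@positions
  vals <- vapply(lags, function(D) {
    horizon <- T - D
    cand <- c(tt, tt - D)
    bp <- sort(unique(c(0, cand[cand > 0 & cand < horizon], horizon)))
    mids <- (bp[-1] + bp[-length(bp)]) / 2
    i <- .posIndex(tt, mids)
    j <- .posIndex(tt, mids + D)
    sum(.squaredDisp(P, i, j) * diff(bp)) / horizon
  }, numeric(1))
  new("MSDCurve", times = as.numeric(lags), values = vals * traj@ell0^2,
      averaging = "time", nTracks = 1L, T = as.numeric(T))
}

#' Ensemble MSD over many trajectories
#'
#' Mean over tracks of `|r(t) - r(0)|^2` at each requested time, positions
#' interpolated as right-continuous step functions.
#'
#' @param trajs list of [Trajectory-class] objects (>= 1; at least 2 for a
#'   meaningful ensemble).
#' @param times evaluation times; default: log grid over the common horizon.
#' @return an [MSDCurve-class] with `averaging = "ensemble"`.
#' @export
ensembleMSD <- function(trajs, times = NULL) {
  if (length(trajs) == 0) stop("empty track set")
  stopifnot(all(vapply(trajs, is, TRUE, "Trajectory")))
  horizon <- min(vapply(trajs, .horizon, numeric(1)))
  if (is.null(times)) {
    if (horizon <= 1) stop("trajectories too short for a default grid")
    times <- logSpacedGrid(max(1, horizon * 1e-4), horizon, 25)
  }
  acc <- matrix(0, length(times), length(trajs))
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    idx <- .posIndex(tr@times, pmin(times, max(tr@times)))
    acc[, k] <- .squaredDisp(tr@positions, rep(1L, length(idx)), idx) *
      tr@ell0^2
  }
  new("MSDCurve", times = as.numeric(times), values = rowMeans(acc),
      averaging = "ensemble", nTracks = length(trajs),
      T = as.numeric(horizon))
}

#' Fit a power-law scaling exponent to an MSD curve
#'
#' Ordinary least squares of `log(MSD)` on `log(t)` over a fit window:
#' `MSD(t) = prefactor * t^exponent`. The default window discards the first
#' and last half-decade of available abscissa, where transients and poor
#' statistics bias the slope.
#'
#' @param curve an [MSDCurve-class] (or anything with positive `times` and
#'   `values` via [msdTimes()] / [msdValues()]).
#' @param window numeric length-2 `[t_lo, t_hi]`; default as above.
#' @return a [ScalingFit-class].
#' @export
fitScaling <- function(curve, window = NULL) {
  t <- msdTimes(curve)
  y <- msdValues(curve)
  if (is.null(window)) {
    span <- log10(max(t) / min(t))
    window <- if (span > 1.5)
      c(min(t) * 10^0.5, max(t) / 10^0.5)
    else range(t)
  }
  keep <- t >= window[1] & t <= window[2] & y > 0
  if (sum(keep) < 5)
    stop("need at least 5 positive points inside the fit window")
  if (any(y[t >= window[1] & t <= window[2]] <= 0))
    stop("nonpositive MSD values inside the fit window")
  lx <- log(t[keep]); ly <- log(y[keep])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  if (!is.finite(r2)) r2 <- 1  # zero-variance (exact) case
  new("ScalingFit", exponent = unname(fit$coefficients[2]),
      prefactor = exp(unname(fit$coefficients[1])),
      window = as.numeric(window), r2 = r2)
}

#' Empirical step-count probabilities
#'
#' `chi_n(t)`: the fraction of tracks that have completed exactly `n` steps
#' by time `t`. For every `t` the probabilities sum to one over `n`.
#'
#' @param trajs list of [Trajectory-class] objects with event times.
#' @param times evaluation times, all within the simulated horizon.
#' @return matrix with one row per time and columns `n = 0, 1, ...`.
#' @export
stepCountProbs <- function(trajs, times) {
  stopifnot(length(trajs) > 0)
  horizon <- min(vapply(trajs, .horizon, numeric(1)))
  if (any(times > horizon + 1e-9))
    stop("times beyond the simulated horizon")
  counts <- vapply(trajs, function(tr) .posIndex(tr@times, times) - 1L,
                   integer(length(times)))
  counts <- matrix(counts, nrow = length(times))
  nmax <- max(counts)
  out <- t(apply(counts, 1, function(cn) tabulate(cn + 1L, nmax + 1L)))
  out <- matrix(out, nrow = length(times)) / length(trajs)
  colnames(out) <- as.character(0:nmax)
  out
}

#' MSD estimated through step-count probabilities
#'
#' Combines the per-step mean square distance on the support, `rbar2[n]`,
#' with the empirical step-count probabilities:
#' `MSD(t) = sum_n rbar2[n] * chi_n(t)`. When `rbar2` is `NULL` it is
#' estimated from the same tracks as the mean of `|r_n - r_0|^2` over tracks
#' with at least `n` events (an internal RWF-style per-step MSD).
#'
#' @param trajs list of CTRW/LCTRW [Trajectory-class] objects.
#' @param rbar2 numeric vector: mean squared displacement after `n` steps,
#'   for `n = 1, 2, ...` (element `n` is step `n`); or `NULL`.
#' @param times evaluation times within the simulated horizon.
#' @return an [MSDCurve-class] with `averaging = "ensemble"`.
#' @export
msdFromStepCounts <- function(trajs, rbar2 = NULL, times) {
  chi <- stepCountProbs(trajs, times)
  nmax <- ncol(chi) - 1L
  if (is.null(rbar2)) {
    sums <- numeric(nmax); cnt <- numeric(nmax)
    for (tr in trajs) {
      P <- tr@positions
      n <- nrow(P) - 1L
      if (n < 1L) next
      upto <- min(n, nmax)
      d2 <- .squaredDisp(P, rep(1L, upto), seq_len(upto) + 1L) * tr@ell0^2
      sums[seq_len(upto)] <- sums[seq_len(upto)] + d2
      cnt[seq_len(upto)] <- cnt[seq_len(upto)] + 1
    }
    rbar2 <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
    # beyond the deepest observed step count, carry the last estimate
    rbar2[is.na(rbar2)] <- rbar2[max(which(!is.na(rbar2)))]
  }
  if (length(rbar2) < nmax) rbar2 <- c(rbar2, rep(rbar2[length(rbar2)],
                                                  nmax - length(rbar2)))
  vals <- as.numeric(chi %*% c(0, rbar2[seq_len(nmax)]))
  new("MSDCurve", times = as.numeric(times), values = vals,
      averaging = "ensemble", nTracks = length(trajs),
      T = as.numeric(max(times)))
}

#' Per-track time-averaged MSD amplitude scatter
#'
#' Computes the time-averaged MSD at a single fixed lag for each track and
#' returns the amplitudes; their coefficient of variation is the operational
#' fingerprint of broken ergodicity (it stays bounded away from zero for
#' heavy-tailed CTRWs no matter how long the measurement).
#'
#' @param trajs list of [Trajectory-class] objects.
#' @param lag fixed lag (one value).
#' @return numeric vector of per-track amplitudes.
#' @export
tamsdAmplitudes <- function(trajs, lag) {
  vapply(trajs, function(tr)
    msdValues(timeAveragedMSD(tr, lags = lag)), numeric(1))
}
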