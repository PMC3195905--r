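#' Heavy-tailed waiting time model
#'
#' Constructs the inverse-gamma waiting time law
#' `psi(t) = exp(-1/t) t^(-(1+gamma)) / Gamma(gamma)` used to model temporal
#' heterogeneity (trapping) of single molecules. Its survival function decays
#' as `t^-gamma`, so for `gamma <= 1` the mean waiting time is infinite and
#' ergodicity is broken on all time scales.
#'
#' @param gamma temporal heterogeneity exponent in (0, 1].
#' @param scale multiplicative time scale (default 1 simulation time unit;
#'   physical calibration is the caller's concern).
#' @return a [WaitingTimeModel-class].
#' @export
waitingTimeModel <- function(gamma, scale = 1) {
  new("WaitingTimeModel", gamma = as.numeric(gamma), scale = as.numeric(scale))
}

#' Sample waiting times
#'
#' Draws i.i.d. waiting times from an inverse-gamma model as reciprocals of
#' gamma-distributed variates: if `X ~ Gamma(shape = gamma, rate = 1)` then
#' `1/X` has density `exp(-1/t) t^-(1+gamma) / Gamma(gamma)`.
#'
#' @param model a [WaitingTimeModel-class].
#' @param n number of draws (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector of `n` waiting times.
#' @export
sampleWaitingTimes <- function(model, n, seed = NULL) {
  stopifnot(is(model, "WaitingTimeModel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  model@scale / stats::rgamma(n, shape = model@gamma, rate = 1)
}

#' Inverse-gamma waiting-time distribution functions
#'
#' Density and distribution function of the scale-1 inverse-gamma waiting
#' law; `pWaitingTime` is the regularized upper incomplete gamma function
#' `Gamma(gamma, 1/t) / Gamma(gamma)`.
#'
#' @param t time (> 0).
#' @param gamma exponent in (0, 1].
#' @return numeric vector.
#' @export
dWaitingTime <- function(t, gamma) {
  exp(-1 / t) * t^(-(1 + gamma)) / gamma(gamma)
}

#' @rdname dWaitingTime
#' @export
pWaitingTime <- function(t, gamma) {
  stats::pgamma(1 / t, shape = gamma, rate = 1, lower.tail = FALSE)
}

newTrajectory <- function(times, positions, kind, gamma = 1, support = NULL,
                          seed = NA_integer_, ell0 = 1, rmax = Inf,
                          meta = list()) {
  storage.mode(positions) <- "integer"
  dimnames(positions) <- NULL
  new("Trajectory", times = as.numeric(times), positions = positions,
      kind = kind, gamma = as.numeric(gamma), support = support,
      seed = as.integer(if (is.null(seed)) NA else seed), ell0 = ell0,
      rmax = rmax, meta = meta)
}

#' Brownian lattice track
#'
#' `n` i.i.d. unit steps on the free integer lattice, each of the `2*dim`
#' signed coordinate directions drawn with equal probability, one time unit
#' per step.
#'
#' @param n number of steps (`n = 0` gives a single point at the origin).
#' @param dim 2 or 3.
#' @param seed optional integer seed.
#' @param start integer start coordinates (default the origin).
#' @return a [Trajectory-class] of kind `"brownian"`.
#' @export
brownianTrack <- function(n, dim = 3L, seed = NULL, start = rep(0L, dim)) {
  stopifnot(n >= 0, dim %in% c(2, 3), length(start) == dim)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(newTrajectory(0, matrix(as.integer(start), 1), "brownian",
                         seed = seed))
  d <- sample.int(2L * dim, n, replace = TRUE)
  axis <- (d + 1L) %/% 2L
  sgn <- ifelse(d %% 2L == 0L, 1L, -1L)
  steps <- matrix(0L, n, dim)
  steps[cbind(seq_len(n), axis)] <- sgn
  pos <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
  newTrajectory(0:n, pos, "brownian", seed = seed)
}

#' Blind-ant random walk on a fractal support (RWF)
#'
#' At each tick a uniformly random neighbor is proposed; the move is taken
#' iff the target site is accessible (and inside the stage-`kmax` bounding
#' box), otherwise the walker stays in place and the tick is still consumed
#' (blind ant). Constant unit time per tick.
#'
#' @param support a [FractalSupport-class].
#' @param n number of ticks.
#' @param start accessible start site (0-based integer coordinates; default
#'   the origin).
#' @param seed optional integer seed.
#' @return a [Trajectory-class] of kind `"rwf"`.
#' @export
rwfWalk <- function(support, n, start = rep(0L, spaceDim(support)),
                    seed = NULL) {
  stopifnot(is(support, "FractalSupport"), n >= 1)
  if (!isAccessible(start, support))
    stop("start site is not accessible on the support")
  if (!is.null(seed)) set.seed(seed)
  gen <- support@generator
  pos <- cpp_blind_ant_walk(as.integer(n), as.integer(start), TRUE,
                            as.logical(gen@allowed), gen@nu, support@kmax,
                            Inf)
  newTrajectory(0:n, pos, "rwf", support = support, seed = seed)
}

# Draw waiting times until their cumulative sum exceeds `T`; returns the
# event times (cumsum) with at least one element beyond T, growing in chunks
# so heavy tails do not force a size guess.
drawEventTimes <- function(model, T, chunk = 256L) {
  w <- sampleWaitingTimes(model, chunk)
  tc <- cumsum(w)
  while (tc[length(tc)] <= T) {
    w <- sampleWaitingTimes(model, chunk)
    tc <- c(tc, tc[length(tc)] + cumsum(w))
  }
  tc
}

#' Continuous-time random walk (CTRW)
#'
#' Blind-ant stepping as in [rwfWalk()] (or free Brownian stepping when
#' `support` is `NULL`), with each step preceded by an independent
#' heavy-tailed waiting time: the molecule waits on each site before moving.
#' The simulation stops at the first event time exceeding `T`; recorded
#' events are those with time at most `T`, and between events the position
#' is the last visited site.
#'
#' @param support a [FractalSupport-class], or `NULL` for the free lattice.
#' @param model a [WaitingTimeModel-class], or a numeric deterministic
#'   waiting time (then every step takes exactly that long).
#' @param T total simulated time (> 0).
#' @param start start site (default origin).
#' @param seed optional integer seed.
#' @param dim spatial dimension when `support` is `NULL`.
#' @return a [Trajectory-class] of kind `"ctrw"`.
#' @export
ctrwWalk <- function(support, model, T, start = NULL, seed = NULL,
                     dim = 3L) {
  .limitedCtrw(support, model, T, start, seed, dim, rmax = Inf,
               kind = "ctrw", counting = NULL)
}

#' Limited continuous-time random walk (LCTRW)
#'
#' A [ctrwWalk()] under two single-molecule limits: (a) a geometric cap --
#' proposed steps that would take the molecule farther than `rmax` (in
#' `ell0` lattice units, Euclidean) from its start are rejected like blocked
#' sites, so the attainable MSD is bounded by `rmax^2`; the cap models the
#' finite size of the cell or nucleus. (b) the single-occupancy condition --
#' when a [CountingConfig-class] is supplied, the run refuses configurations
#' whose mean occupancy `C = cm * NA * dV` is >= 1, because two or more
#' molecules in the observation volume alias the single-molecule signal.
#'
#' @inheritParams ctrwWalk
#' @param rmax geometric displacement cap in lattice units (`Inf` removes
#'   the limit, recovering [ctrwWalk()] exactly, including the random
#'   stream). A natural choice is the mean interaction size `rbar` of an
#'   [ExposureModel-class] expressed in `ell0` units.
#' @param counting optional [CountingConfig-class] whose occupancy must
#'   satisfy `C < 1`.
#' @return a [Trajectory-class] of kind `"lctrw"`.
#' @export
lctrwWalk <- function(support, model, T, start = NULL, seed = NULL,
                      dim = 3L, rmax = Inf, counting = NULL) {
  .limitedCtrw(support, model, T, start, seed, dim, rmax, "lctrw", counting)
}

.limitedCtrw <- function(support, model, T, start, seed, dim, rmax, kind,
                         counting) {
  if (T <= 0) stop("T must be positive")
  if (rmax <= 0) stop("rmax must be positive")
  meta <- list()
  if (!is.null(counting)) {
    stopifnot(is(counting, "CountingConfig"))
    C <- expectedCount(counting@cm, counting@dV)
    if (C >= 1)
      stop(sprintf(paste0(
        "single-molecule condition violated: occupancy C = %.3g >= 1 ",
        "(expect aliasing by two or more molecules in the volume)"), C))
    meta$C <- C
  }
  if (!is.null(support)) {
    stopifnot(is(support, "FractalSupport"))
    dim <- spaceDim(support)
  }
  if (is.null(start)) start <- rep(0L, dim)
  if (!is.null(support) && !isAccessible(start, support))
    stop("start site is not accessible on the support")
  if (!is.null(seed)) set.seed(seed)
  deterministic <- is.numeric(model)
  if (deterministic) {
    stopifnot(model > 0)
    tcum <- seq(model, T + model, by = model)
    gamma <- 1
  } else {
    stopifnot(is(model, "WaitingTimeModel"))
    tcum <- drawEventTimes(model, T)
    gamma <- model@gamma
  }
  meta$T <- T
  times <- c(0, tcum[tcum <= T])
  n <- length(times) - 1L
  pos <- if (n == 0L) {
    matrix(as.integer(start), 1)
  } else if (is.null(support)) {
    cpp_blind_ant_walk(n, as.integer(start), FALSE, logical(0), 0L, 0L,
                       if (is.finite(rmax)) rmax^2 else Inf)
  } else {
    gen <- support@generator
    cpp_blind_ant_walk(n, as.integer(start), TRUE, as.logical(gen@allowed),
                       gen@nu, support@kmax,
                       if (is.finite(rmax)) rmax^2 else Inf)
  }
  newTrajectory(times, pos, kind, gamma = gamma, support = support,
                seed = seed, rmax = rmax, meta = meta)
}
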