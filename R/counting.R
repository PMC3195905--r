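#' Avogadro constant (2019 SI exact value), mol^-1
#' @export
AVOGADRO <- 6.02214076e23

#' Mean molecular occupancy of the observation volume
#'
#' `C = cm * N_A * dV`: the dimensionless mean number of molecules of bulk
#' molar concentration `cm` inside the observation volume `dV`.
#'
#' @param cm molar bulk concentration (mol/L).
#' @param dV observation volume (L), femtoliter scale in confocal setups.
#' @return dimensionless occupancy `C`.
#' @examples
#' expectedCount(1e-9, 0.14e-15)  # ~0.0843
#' @export
expectedCount <- function(cm, dV) {
  if (any(cm <= 0) || any(dV <= 0)) stop("cm and dV must be positive")
  cm * AVOGADRO * dV
}

#' Poisson probability of counting x molecules
#'
#' `P(x) = C^x e^-C / x!`. The single-molecule probability is
#' `N = P(1) = C e^-C`, so `ln N = ln C - C`; for small `C` (`C << e^-C`),
#' `N ~ C`.
#'
#' @param x non-negative integer count(s).
#' @param C mean occupancy (>= 0).
#' @return probability.
#' @export
poissonCountProb <- function(x, C) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  if (any(C < 0)) stop("C must be non-negative")
  stats::dpois(x, C)
}

#' Concentration cutoff of the single-molecule regime
#'
#' The bulk concentration at which the mean occupancy reaches one molecule
#' per observation volume: `c* = 1 / (N_A * dV)`. Above `c*` the
#' single-molecule condition `N < 1` fails and counts of two, three, ...
#' molecules alias the signal.
#'
#' @param dV observation volume (L).
#' @return molar concentration (mol/L).
#' @examples
#' singleMoleculeCutoff(0.14e-15)  # ~1.19e-8 M, i.e. about 12 nM
#' @export
singleMoleculeCutoff <- function(dV) {
  if (any(dV <= 0)) stop("dV must be positive")
  1 / (AVOGADRO * dV)
}

#' Meaningful time for observing one single molecule
#'
#' `Tm = (tauD / C) * exp(-C)` with `C = cm * N_A * dV`: the expected
#' duration over which one and the same molecule can be observed in the
#' volume before exchange with the bulk makes the record a different
#' molecule. Strictly decreasing in `C` on (0, 1]; diverges as the solution
#' is diluted.
#'
#' @param tauD diffusion time (s).
#' @param cm molar bulk concentration (mol/L).
#' @param dV observation volume (L).
#' @return meaningful time (s).
#' @examples
#' meaningfulTime(1e-3, singleMoleculeCutoff(1e-15), 1e-15)  # exp(-1) ms
#' @export
meaningfulTime <- function(tauD, cm, dV) {
  if (any(tauD <= 0)) stop("tauD must be positive")
  C <- expectedCount(cm, dV)
  if (any(C >= 1))
    warning("occupancy C >= 1: outside the single-molecule regime")
  tauD / C * exp(-C)
}

#' Single-molecule track budget
#'
#' `N_lmax = T / Tm`: how many different single molecules of the same kind
#' are recorded over a measurement of duration `T` when each is observable
#' for the meaningful time `Tm`.
#'
#' @param T measurement time (s).
#' @param Tm meaningful time (s).
#' @return list with `value` (real ratio) and `count` (floor integer).
#' @export
trackBudget <- function(T, Tm) {
  if (any(T <= 0) || any(Tm <= 0)) stop("T and Tm must be positive")
  list(value = T / Tm, count = as.integer(floor(T / Tm)))
}

#' Counting configuration and derived quantities
#'
#' Bundles the experimental counting parameters; [countingSummary()]
#' evaluates the occupancy, single-molecule probability, concentration
#' cutoff, meaningful time and track budget in one call.
#'
#' @param cm molar bulk concentration (mol/L).
#' @param dV observation volume (L).
#' @param tauD diffusion time (s).
#' @param T measurement time (s).
#' @return a [CountingConfig-class].
#' @export
countingConfig <- function(cm, dV, tauD, T) {
  new("CountingConfig", cm = as.numeric(cm), dV = as.numeric(dV),
      tauD = as.numeric(tauD), T = as.numeric(T))
}

#' @rdname countingConfig
#' @param config a [CountingConfig-class].
#' @export
countingSummary <- function(config) {
  stopifnot(is(config, "CountingConfig"))
  C <- expectedCount(config@cm, config@dV)
  Tm <- suppressWarnings(meaningfulTime(config@tauD, config@cm, config@dV))
  budget <- trackBudget(config@T, Tm)
  list(C = C, N = poissonCountProb(1L, C),
       cutoff = singleMoleculeCutoff(config@dV), Tm = Tm,
       NlmaxReal = budget$value, Nlmax = budget$count,
       singleMolecule = C < 1)
}

#' Aliasing probability: two or more molecules in the volume
#'
#' `P(X >= 2) = 1 - e^-C (1 + C)` under the Poisson occupancy law; the rate
#' at which sampling epochs are contaminated by multi-molecule events.
#'
#' @param C mean occupancy.
#' @return probability.
#' @export
aliasingProb <- function(C) {
  if (any(C < 0)) stop("C must be non-negative")
  stats::ppois(1, C, lower.tail = FALSE)
}
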