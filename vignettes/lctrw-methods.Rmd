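---
title: "Models and methods behind lctrw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lctrw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lctrw)
```

## The model

A molecule diffusing in a cell is hindered in two distinct ways. *Crowding*
is spatial: obstacles of every size block paths, which we idealize as a
random walk on a generalized Sierpinski carpet (GSC) — a self-similar
lattice with holes on all length scales. A blind-ant walk on such a support
(constant time per tick, blocked proposals consume the tick) has

$$\langle r^2(n)\rangle \propto n^{\alpha}, \qquad 0 < \alpha < 1 .$$

*Temporal heterogeneity* is kinetic: binding to ligands and complexes traps
the molecule for random waiting times. We draw waits from the inverse-gamma
law

$$\psi(t) = \frac{e^{-1/t}\,t^{-(1+\gamma)}}{\Gamma(\gamma)},
  \qquad 0 < \gamma \le 1,$$

whose survival function decays as $t^{-\gamma}$; the mean waiting time is
infinite, so the central limit theorem fails and ergodicity is broken on
every time scale. Superimposing both mechanisms (a CTRW on a fractal
support) decouples them in the MSD exponent:

$$\langle r^2(t)\rangle \propto t^{\alpha\gamma} = t^{\tilde\gamma}.$$

The *limited* CTRW (LCTRW) adds two constraints of real single-molecule
experiments: a geometric cap — displacements beyond $r_{max}$ (the cell or
nucleus size) are rejected like blocked sites, so the MSD saturates at
$r_{max}^2$ — and the single-occupancy condition $N < 1$, where
$N = P(X=1) = C e^{-C}$ is the Poisson probability of one molecule in the
observation volume at mean occupancy $C = c_m N_A \Delta V$. Configurations
with $C \ge 1$ are refused outright, because counts of two or more
molecules alias the single-molecule signal.

## Fractal supports and accessibility

A support is defined only by its generator mask (a $\nu^{dim}$ 0/1 grid
deleting at most half its cells) and an iteration depth $k_{max}$; the
lattice is never materialized. A site is accessible iff, at every stage
from its own down to 1, the coarse cell $\lfloor x_i/\nu^{k-1}\rfloor$ is
allowed, with coordinates carried over as $x_i \bmod \nu^{k-1}$. Coordinates
are 0-based and the stage bracket $[\nu^{k-1}, \nu^k)$ is half-open, which
makes the integer-part/modulo update exact. Two consequences are used as
test oracles: the number of accessible sites in the stage-$k$ box is
(allowed cells)$^k$, and the iterative check equals a recursive
digit-by-digit oracle site by site. Shipped masks keep the origin cell
allowed so walks may start at the origin; other start sites are validated
at walk setup. The stage-$k_{max}$ bounding box blocks (reflects) proposals
beyond it, consistent with blind-ant semantics.

## MSD estimators and scaling fits

CTRW trajectories are right-continuous step functions (the molecule waits
*on* its site). The time-averaged MSD

$$\overline{\delta^2}(\Delta) = \frac{1}{T-\Delta}\int_0^{T-\Delta}
  \left|r(t+\Delta)-r(t)\right|^2 dt$$

is integrated exactly over the piecewise-constant partition, so no
time-discretization error enters. Ensemble averages evaluate
$|r(t)-r(0)|^2$ across tracks; the step-count estimator recombines the
per-step MSD $\bar r^2_n$ with the empirical fraction $\hat\chi_n(t)$ of
tracks that completed exactly $n$ steps by $t$ (its closed-form Laplace
counterpart is deliberately out of scope — the empirical estimator is
unbiased and testable against the direct average). Scaling exponents are
ordinary least squares of $\log$ MSD on $\log t$; the default window
discards the first and last half-decade, where transients (e.g. the corner
effect of walks started at the origin of the bounding box) and poor
statistics bias the slope. The power-law prefactor is always a *free*
fitted amplitude; the gamma-function value $\Gamma(\tilde\gamma)$ is used
only as the default amplitude when generating ideal synthetic curves.

## The subpopulation minimization

Given ideal single-molecule curves
$f_\ell(t) = \Gamma(\tilde\gamma_\ell)\, t^{\tilde\gamma_\ell}$ with
exponents ordered as
$\tilde\gamma_\ell = \tilde\gamma_{min} + \ell\,\Delta\tilde\gamma$,
$\Delta\tilde\gamma = (\tilde\gamma_{max}-\tilde\gamma_{min})/\ell_{max}$,
the subpopulation exponent $\tilde\gamma_{sub}$ is the OLS slope of the log
of the *mean* curve against $\log t$ (the only reading under which the
power laws become linear; the alternative regressor $t_i$ makes every
variation curve flat and is rejected). Scanning
$|\tilde\gamma - \tilde\gamma_{sub}|$ over $\ell_{max}$ locates a global
minimum at a small track count, then a plateau — the operational statement
that a small subpopulation average of non-ergodic tracks mimics an ergodic
exponent.

**Calibration of the measurement window.** The published analysis states
the bounds ([0.243, 0.799] for target 0.689), the gamma-function prefactor
convention and the optimum of 32 tracks, but not the measurement grid
$[a, b]$ — and the minimizer depends sensitively on $b$. We therefore
calibrated the default window once against the published optimum: with
$[a,b] = [1, 8\times 10^9]$ simulation time units at 25 log-spaced points
per decade, the reference configuration attains its global minimum at
$\ell_{max}^\ast = 32$, stably for 15–40 points per decade, and reproduces
the published ordering of variation curves across
$\tilde\gamma_{max} \in \{0.785, 0.795, 0.797, 0.799, 0.8\}$. A window of
$[1, 10^4]$, by contrast, puts the minimum at 3. Both the grid and the
prefactor rule remain arguments of every subpopulation function, so any
other convention is one call away.

The bound optimization (`optimizeBounds`) grid-searches
$(\tilde\gamma_{min}, \tilde\gamma_{max})$ under the containment constraint
$\tilde\gamma_{min} \le \tilde\gamma_{sub} \le \tilde\gamma_{max}$. Its
default resolution is 0.005 — the published map's 0.00078125 is accepted
but costs an $O(10^6)$-candidate scan; correctness is
resolution-independent. Ties in the $\ell_{max}$ argmin break toward the
smallest count, matching the emphasis that the optimum is a small number.
The degenerate candidate interval $[\tilde\gamma, \tilde\gamma]$ (variation
identically zero) is admitted only on request (`allowDegenerate`), since it
trivializes the scan whenever the target lies on the candidate grid.

## FCS, counting and exposure

The correlation model
$G(\tau) = \frac{1}{N}\left[1+(\tau/\tau_D)^{\tilde\gamma}\right]^{-1}
\left[1+\frac{1}{s^2}(\tau/\tau_D)^{\tilde\gamma}\right]^{-(dim-2)/2} + 1$
satisfies $G(0)-1 = 1/N$, reduces to the classical single-component form at
$\tilde\gamma = 1$, $dim = 3$, and drops its axial factor at $dim = 2$.
Two-color cross-correlation uses the same functional form; channel
amplitude calibration is out of scope. The anomalous diffusion time is
implemented as the closed form
$\tau_D = \left[\omega^2\, 2\,dim/(4 m \Gamma_{\tilde\gamma})\right]^{1/\tilde\gamma}$
and asserted to be the fixed point of $\tau = \omega^2/(4 m D_{app}(\tau))$,
which makes the typographically compressed published expression testable.
The inverse problem fits $(N, \tau_D, \tilde\gamma)$ by
Levenberg–Marquardt with $N, \tau_D$ in log-space (positivity) and
$\tilde\gamma$ bounded to $(0.05, 1.5]$ so boundary solutions remain
detectable.

Counting uses the exact 2019 SI Avogadro constant. For
$\Delta V = 0.14$ fL the $C = 1$ cutoff computes to 11.9 nM; the published
"about 11 nM" is treated as a rounded figure, and calculators warn (rather
than fail) above the cutoff — only LCTRW *simulation* setup makes $C \ge 1$
a hard error. The exposure moments are taken over the power-law density on
$[0, r_{max}]$ (where they are exact), not the untruncated Weibull: for
$q = 2$, $r_{max} = 22.8$ µm this gives $\bar r = 15.2$ µm,
$\sigma_r^2 = 28.88$ µm², MSD cap $\bar r^2 = 2.31\times 10^{-10}$ m².
(The companion figure $\pm 2.92\times 10^{-11}$ m² printed alongside the
published variance is inconsistent with the variance's own value of
$2.888\times 10^{-11}$ m²; the derived value is asserted.) The LCTRW cap
radius defaults to $\bar r$, not $r_{max}$, so the attainable MSD equals
the exposure model's cap.

## What the synthetic generator does and does not emulate

Simulated conditions follow the published study: the standard 3×3 carpet at
stage 6, waiting exponents $\gamma \in (0, 1]$ with scale 1 simulation time
unit (physical calibration is the caller's concern), walks started at the
origin, ideal power-law families for the subpopulation machinery, and
noiseless or 1 %-noise correlation curves. Real data differ in ways the
generator deliberately ignores: photophysics (blinking, bleaching),
detector noise and afterpulsing, active transport ($\tilde\gamma > 1$),
continuum off-lattice motion, and disordered (percolation-type) obstacles.
Passing tests therefore validate the estimators and the minimization logic
under the stated model, not the biology of any particular cell.

## Problem sizes and numerical choices

Test and acceptance runs use 300–500 tracks of $10^4$–$10^5$ steps (walk
horizons up to $10^8$ time units for CTRWs on the carpet, so the walk
reaches the step range over which $\alpha$ is fitted); these sizes put the
group-split standard error of fitted exponents near 0.01, small enough to
separate $\alpha < 1$ from normal diffusion. Waiting times are sampled as
reciprocals of gamma variates (exact, no rejection). Scaling-fit windows
exclude transients as described above; exponent confidence intervals come
from splitting tracks into 10 groups. Blocked blind-ant proposals consume
their tick (and, in CTRWs, their waiting time) — the blind ant, not the
myopic ant. The Methods wording that the waiting law "is a stable Levy
distribution" is read as loose phrasing for the same heavy-tailed family;
the inverse-gamma density is stated explicitly twice and is what is
implemented, behind a pluggable model object.

## Known limitations

* The subpopulation window calibration reproduces the published optimum
  but cannot be verified against the original grid, which was never
  stated.
* `optimizeBounds` at the published resolution is an overnight-scale scan;
  the default coarsens it.
* Sub-ensemble commutativity (time average of the mean vs mean of time
  averages) is checked empirically in tests, not assumed in code paths.
* The occupancy condition is enforced at configuration level; the arrival/
  departure (reentry) process itself is not simulated beyond the
  $p_{n,\bar n} = 1 - p_{n,n} = N$ identity.
* Fractal-dimension estimation, Lévy flights in space, and analytic
  Laplace inversion of the step-count law are out of scope.
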