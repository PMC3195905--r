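# lctrw

Simulation and analysis of anomalous subdiffusion of single molecules in
the crowded interior of living cells, built around *limited continuous-time
random walks* (LCTRW) on fractal supports.

## The problem and who this is for

Single-molecule fluorescence experiments (FCS, two-color FCCS, single
particle tracking) routinely find subdiffusive motion in cells: the mean
square displacement grows as

    MSD(t) = Γ · t^γ̃ ,   γ̃ = α · γ < 1

where the overall anomaly exponent factorizes into a *spatial* part α
(molecular crowding, modeled as a random walk on a generalized Sierpinski
carpet) and a *temporal* part γ (trapping by interactions, modeled by
heavy-tailed inverse-gamma waiting times). Heavy-tailed waiting breaks
ergodicity: time averages along one trajectory and ensemble averages over
many no longer agree. The package's central result is the subpopulation
averaging minimization: averaging a surprisingly small, optimally chosen
number of non-ergodic single-molecule tracks reproduces the scaling of an
ergodic measurement — so broken and unbroken ergodicity become
experimentally indistinguishable. The toolkit is for biophysicists who
simulate, fit or design such experiments.

What is implemented:

* **Fractal supports** — generalized Sierpinski carpets from a 0/1
  generator mask, with on-demand site accessibility by stage-wise
  renormalization (`fractalSupport`, `isAccessible`).
* **Walkers** — Brownian lattice tracks, blind-ant walks on fractals (RWF),
  CTRWs with inverse-gamma waiting times, and LCTRWs with a geometric
  displacement cap and the single-occupancy condition N < 1
  (`brownianTrack`, `rwfWalk`, `ctrwWalk`, `lctrwWalk`).
* **MSD estimators** — exact piecewise-constant time averages, ensemble and
  sub-ensemble averages, step-count (χₙ) estimation, log–log scaling fits
  (`timeAveragedMSD`, `ensembleMSD`, `msdFromStepCounts`, `fitScaling`).
* **Subpopulation minimization** — ideal power-law track families, the
  closed-form OLS subpopulation fit, the variation scan over the number of
  tracks and the bound optimization (`buildFamily`, `fitSubpopulation`,
  `scanVariation`, `optimizeBounds`, `subsampleTracks`).
* **FCS** — the anomalous-diffusion correlation model
  G(τ) = (1/N)[1+(τ/τ_D)^γ̃]⁻¹[1+(1/s²)(τ/τ_D)^γ̃]^−(dim−2)/2 + 1 and its
  inverse problem, plus D_app(t), D_inst(t) and the anomalous diffusion
  time (`correlationModel`, `fitCorrelation`, `dApp`, `dInst`,
  `diffusionTime`).
* **Counting** — Poisson occupancy statistics of the femtoliter observation
  volume, the single-molecule cutoff concentration, the meaningful time
  T_m = (τ_D/C)e^−C and the track budget N = T/T_m (`expectedCount`,
  `singleMoleculeCutoff`, `meaningfulTime`, `trackBudget`).
* **Exposure** — the Weibull/power-law model of cumulative exposure to
  interaction sites whose mean interaction size sets the LCTRW's MSD cap
  (`exposureModel`, `exposureMoments`, `capRadius`).

## Worked example

```r
library(lctrw)

# where is the optimum subpopulation size for a measured exponent 0.689?
sv <- scanVariation(0.689, gmin = 0.243, gmax = 0.799, lrange = 1:200)
sv$lmaxOpt
#> [1] 32

# single-molecule counting for a 0.14 fL confocal volume at 5 nM
countingConfig(cm = 5e-9, dV = 0.14e-15, tauD = 1e-3, T = 10)
#> CountingConfig: cm = 5e-09 M, dV = 1.4e-16 L, tauD = 0.001 s, T = 10 s
#>   C = 0.4215, N = P(1) = 0.2765, cutoff = 1.186e-08 M, Tm = 0.001556 s, N_lmax = 6426

# the geometric MSD cap of a HeLa nucleus (r_max = 22.8 um, q = 2)
exposureModel(rmax = 22.8e-6, q = 2)
#> ExposureModel: rmax = 2.28e-05 m, q = 2
#>   rbar = 1.52e-05 m, sigma_r^2 = 2.888e-11 m^2, MSD cap = 2.31e-10 m^2

# an LCTRW capped at the mean interaction size, on a stage-6 carpet
supp <- fractalSupport(standardCarpetMask(), kmax = 6)
tr <- lctrwWalk(supp, waitingTimeModel(0.5), T = 1e6, seed = 1, rmax = 15.2)
fitScaling(timeAveragedMSD(tr))
```

Reading the output: 32 is the number of randomly selected single-molecule
tracks at which the subpopulation exponent γ̃_sub comes closest to the
target γ̃ = 0.689; C is the mean occupancy of the volume (0.42 molecules,
safely below the ≈ 11.9 nM cutoff where C = 1); T_m ≈ 1.6 ms is how long
one and the same molecule is observed before bulk exchange, so a 10 s
record holds ≈ 6426 different molecules; 2.31·10⁻¹⁰ m² is the upper
limiting value of the MSD imposed by the nucleus geometry.

A command-line wrapper with `simulate`, `msd`, `subpop`, `fcs`,
`counting`, `exposure` and `fixtures` subcommands is installed at
`system.file("scripts", "lctrw", package = "lctrw")`.

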