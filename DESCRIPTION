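Package: lctrw
Title: Limited Continuous-Time Random Walks on Fractal Supports for
    Single-Molecule Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for anomalous subdiffusion of
    single molecules in crowded cellular environments. Builds generalized
    Sierpinski carpet supports from a generator mask, runs blind-ant random
    walks, continuous-time random walks (CTRW) with heavy-tailed
    inverse-gamma waiting times, and limited CTRWs (LCTRW) capped by the
    geometric size of the cell or nucleus under the single-molecule
    occupancy condition N < 1. Provides time-averaged, ensemble and
    sub-ensemble mean square displacement (MSD) estimators with power-law
    scaling fits, the subpopulation-averaging minimization that renders
    broken and unbroken ergodicity indistinguishable, the anomalous-diffusion
    fluorescence correlation spectroscopy (FCS) model with time-dependent
    apparent diffusion quantities, Poisson single-molecule counting
    calculators (meaningful time, track budget), and the Weibull/power-law
    exposure model that supplies the MSD cap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
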