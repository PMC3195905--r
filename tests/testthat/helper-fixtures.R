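# Shared fixtures and small oracles, all built in code.

carpetSupport <- function(kmax = 2L)
  fractalSupport(standardCarpetMask(), kmax = kmax)

# A seeded random GSC generator with the origin cell allowed and at most
# half of the cells deleted.
randomMask <- function(nu = 3L, dim = 2L, seed = 1L) {
  set.seed(seed)
  n <- nu^dim
  nDelete <- sample.int(floor(n / 2), 1)
  del <- sample(2:n, nDelete)  # never delete cell 1 (the origin)
  allowed <- rep(TRUE, n)
  allowed[del] <- FALSE
  generatorMask(array(allowed, dim = rep(nu, dim)))
}

# Ensemble-MSD scaling exponent with a group-split standard error:
# tracks are split into ngroups, the slope fitted per group, and the
# mean/SE of the group slopes returned.
groupSlopes <- function(trajs, times, window, ngroups = 10) {
  idx <- split(seq_along(trajs), rep(seq_len(ngroups),
                                     length.out = length(trajs)))
  slopes <- vapply(idx, function(i)
    scalingExponent(fitScaling(ensembleMSD(trajs[i], times), window)),
    numeric(1))
  list(mean = mean(slopes), se = stats::sd(slopes) / sqrt(ngroups),
       slopes = slopes)
}

# Brute-force 2-D grid search oracle for the subpopulation fit: minimizes
# the sum of squared log-residuals over an explicit (gsub, csub) grid.
gridSearchSubpop <- function(family, gRange, cRange, n = 201) {
  y <- log(colMeans(family@curves))
  x <- log(family@grid)
  gs <- seq(gRange[1], gRange[2], length.out = n)
  cs <- seq(cRange[1], cRange[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (g in gs) {
    # for fixed g the optimal c is the mean residual; scanning both anyway
    sse <- vapply(cs, function(cc) sum((y - g * x - cc)^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < best[3]) best <- c(g, cs[i], sse[i])
  }
  list(gsub = best[1], csub = best[2], sse = best[3])
}
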