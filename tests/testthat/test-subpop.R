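smallGrid <- logSpacedGrid(1, 1e4, 25)

test_that("ideal track families are built with ordered exponents", {
  f1 <- buildFamily(0.2, 0.8, 1, grid = smallGrid)
  expect_equal(f1@exponents, 0.8)

  f2 <- buildFamily(0.2, 0.8, 2, grid = smallGrid, prefactor = "unit")
  expect_equal(f2@exponents, c(0.5, 0.8))
  expect_true(all(diff(f2@exponents) > 0))
  # unit prefactors: every curve passes through 1 at t = 1
  expect_equal(unname(f2@curves[, 1]), c(1, 1))

  fg <- buildFamily(0.3, 0.7, 5, grid = smallGrid, prefactor = "gamma")
  expect_equal(fg@prefactors, gamma(fg@exponents))

  expect_error(buildFamily(0.8, 0.2, 3, grid = smallGrid), "gmin < gmax")
  expect_error(buildFamily(0, 0.5, 3, grid = smallGrid), "gmin")
})

test_that("subpopulation fit equals the brute-force grid-search oracle", {
  set.seed(10)
  for (i in 1:5) {
    gmin <- stats::runif(1, 0.1, 0.4)
    gmax <- stats::runif(1, gmin + 0.1, 0.9)
    lmax <- sample(2:20, 1)
    fam <- buildFamily(gmin, gmax, lmax, grid = smallGrid,
                       prefactor = sample(c("unit", "gamma"), 1))
    fit <- fitSubpopulation(fam)
    oracle <- gridSearchSubpop(fam, gRange = c(fit$gsub - 0.05,
                                               fit$gsub + 0.05),
                               cRange = c(fit$csub - 0.2, fit$csub + 0.2))
    expect_lt(abs(fit$gsub - oracle$gsub), 1e-3)
    expect_lt(abs(fit$csub - oracle$csub), 4e-3)
  }
})

test_that("single-exponent families are recovered exactly", {
  fam <- buildFamily(0.2, 0.65, 1, grid = smallGrid, prefactor = "unit")
  fit <- fitSubpopulation(fam)
  expect_equal(fit$gsub, 0.65, tolerance = 1e-12)
  expect_equal(fit$csub, 0, tolerance = 1e-10)
})

test_that("rescaling the mean curve shifts only the log-prefactor", {
  fam <- buildFamily(0.3, 0.7, 8, grid = smallGrid)
  fit <- fitSubpopulation(fam)
  scaled <- fam
  scaled@curves <- fam@curves * 3.7
  fit2 <- fitSubpopulation(scaled)
  expect_equal(fit2$gsub, fit$gsub, tolerance = 1e-12)
  expect_equal(fit2$csub, fit$csub + log(3.7), tolerance = 1e-10)
})

test_that("the subpopulation exponent stays inside the bounds", {
  # monotone envelope for unit prefactors over many family sizes
  sv <- scanVariation(0.5, 0.25, 0.75, lrange = 1:60, grid = smallGrid,
                      prefactor = "unit")
  expect_true(all(sv$curve$gsub >= 0.25 & sv$curve$gsub <= 0.75))
})

test_that("variation scan finds its minimum and plateaus", {
  sv <- scanVariation(0.689, 0.243, 0.799, lrange = 1:200)
  expect_identical(sv$lmaxOpt, 32L)
  v <- sv$curve$variation
  expect_lt(min(v), 1e-3)
  # stable plateau: late values vary little and sit above the minimum
  late <- v[sv$curve$lmax >= 150]
  expect_lt(stats::sd(late) / mean(late), 0.05)
  expect_gt(min(late), 10 * min(v))
})

test_that("bound optimization honors the containment constraint", {
  res <- optimizeBounds(0.55, resolution = 0.05, lrange = 1:25,
                        grid = smallGrid)
  expect_s4_class(res, "SubpopResult")
  expect_gte(res@gsub, res@bounds[1] - 1e-9)
  expect_lte(res@gsub, res@bounds[2] + 1e-9)
  expect_gte(res@lmaxOpt, 1L)
  # the optimized variation beats (or ties) any single candidate interval
  sv <- scanVariation(0.55, 0.25, 0.75, lrange = 1:25, grid = smallGrid)
  expect_lte(res@variation, min(sv$curve$variation) + 1e-12)

  # a candidate interval degenerate at the target yields zero variation
  res0 <- optimizeBounds(0.55, resolution = 0.05, lrange = 1:5,
                         grid = smallGrid, allowDegenerate = TRUE)
  expect_equal(res0@variation, 0)
  expect_identical(res0@lmaxOpt, 1L)
  expect_error(optimizeBounds(0.5, resolution = 0.7), "resolution")
})

test_that("track subsampling is reproducible and honors the bounds", {
  tgrid <- logSpacedGrid(1, 1e3, 10)
  mkCurve <- function(g, A = 1)
    new("MSDCurve", times = tgrid, values = A * tgrid^g,
        averaging = "time", nTracks = 1L, T = 1e3)

  # identical tracks: the averaged exponent is the common exponent
  same <- lapply(1:10, function(i) mkCurve(0.6))
  out <- subsampleTracks(same, bounds = c(0.5, 0.7), n = 5, seed = 1,
                         window = range(tgrid))
  expect_equal(scalingExponent(out$fit), 0.6, tolerance = 1e-10)

  set.seed(2)
  gs <- stats::runif(40, 0.2, 0.9)
  curves <- lapply(gs, mkCurve)
  a <- subsampleTracks(curves, bounds = c(0.3, 0.8), n = 10, seed = 3,
                       window = range(tgrid))
  b <- subsampleTracks(curves, bounds = c(0.3, 0.8), n = 10, seed = 3,
                       window = range(tgrid))
  expect_identical(a$selected, b$selected)
  expect_true(all(gs[a$selected] >= 0.3 & gs[a$selected] <= 0.8))
  expect_error(subsampleTracks(curves, bounds = c(0.89, 0.9), n = 10),
               "inside the bounds")
})

test_that("subset averaging hides broken ergodicity", {
  # individual CTRW displacement curves scatter wildly; a 32-track average
  # recovers an exponent close to the ergodic target alpha*gamma = 0.5
  model <- waitingTimeModel(0.5)
  set.seed(12)
  trs <- lapply(1:150, function(i) ctrwWalk(NULL, model, T = 1e5, dim = 3))
  tgrid <- logSpacedGrid(10, 1e5, 8)
  curves <- lapply(trs, function(tr) ensembleMSD(list(tr), tgrid))
  gs <- vapply(curves, function(cu) {
    v <- msdValues(cu)
    if (any(v[msdTimes(cu) >= 10] <= 0)) return(NA_real_)
    scalingExponent(fitScaling(cu, window = c(10, 1e5)))
  }, numeric(1))
  ok <- which(is.finite(gs))
  bounds <- stats::quantile(gs[ok], c(0.1, 0.9), names = FALSE)
  out <- subsampleTracks(curves[ok], gs[ok], bounds = bounds, n = 32,
                         seed = 13, window = c(10, 1e5))
  subDev <- abs(scalingExponent(out$fit) - 0.5)
  medianDev <- stats::median(abs(gs[ok] - 0.5))
  expect_lt(subDev, medianDev)
  expect_lt(subDev, 0.15)
})
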