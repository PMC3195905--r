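test_that("time-averaged MSD handles degenerate and exact cases", {
  # constant trajectory (all neighbors blocked) -> 0 at every lag
  m <- matrix(TRUE, 3, 3); m[2, 1] <- FALSE; m[1, 2] <- FALSE
  supp <- fractalSupport(generatorMask(m), kmax = 1)
  tr <- rwfWalk(supp, 100, seed = 1)
  ta <- timeAveragedMSD(tr, lags = c(1, 5, 10))
  expect_equal(msdValues(ta), c(0, 0, 0))

  # unit-velocity staircase: at integer lags the TA-MSD equals lag^2
  bal <- lctrw:::newTrajectory(0:100, cbind(0:100, 0L), "rwf")
  tab <- timeAveragedMSD(bal, lags = c(1, 2, 5, 10))
  expect_equal(msdValues(tab), c(1, 2, 5, 10)^2)

  expect_error(timeAveragedMSD(bal, lags = 150), "smaller than T")
  expect_error(timeAveragedMSD(bal, lags = 10, T = 200), "duration")
})

test_that("time-averaged MSD of a Brownian track scales linearly", {
  tr <- brownianTrack(2e4, dim = 3, seed = 2)
  ta <- timeAveragedMSD(tr, lags = logSpacedGrid(1, 2000, 10))
  fit <- fitScaling(ta, window = c(1, 2000))
  expect_equal(scalingExponent(fit), 1, tolerance = 0.05)
})

test_that("ensemble MSD matches the lattice closed form", {
  # single constant track
  m <- matrix(TRUE, 3, 3); m[2, 1] <- FALSE; m[1, 2] <- FALSE
  supp <- fractalSupport(generatorMask(m), kmax = 1)
  one <- ensembleMSD(list(rwfWalk(supp, 50, seed = 3)), times = c(5, 20))
  expect_equal(msdValues(one), c(0, 0))

  # 500 brownian tracks, dim 2: MSD(t) = t = 2*dim*D*t with D = 1/(2*dim)
  set.seed(4)
  trs <- lapply(1:500, function(i) brownianTrack(600, dim = 2))
  times <- c(10, 60, 300, 600)
  em <- ensembleMSD(trs, times)
  perTrack <- vapply(trs, function(tr) {
    idx <- findInterval(times, eventTimes(tr))
    rowSums((positions(tr)[idx, ] - rep(positions(tr)[1, ],
                                        each = length(idx)))^2)
  }, numeric(length(times)))
  se <- apply(perTrack, 1, stats::sd) / sqrt(length(trs))
  expect_true(all(abs(msdValues(em) - times) < 3 * se))

  expect_error(ensembleMSD(list()), "empty")
})

test_that("scaling fits recover exact and noisy power laws", {
  tgrid <- logSpacedGrid(1, 1e4, 10)
  exact <- new("MSDCurve", times = tgrid, values = 2.0 * tgrid^0.689,
               averaging = "ensemble", nTracks = 1L, T = 1e4)
  fit <- fitScaling(exact, window = range(tgrid))
  expect_equal(scalingExponent(fit), 0.689, tolerance = 1e-12)
  expect_equal(scalingPrefactor(fit), 2.0, tolerance = 1e-10)
  expect_equal(fit@r2, 1, tolerance = 1e-12)

  lin <- new("MSDCurve", times = tgrid, values = tgrid,
             averaging = "ensemble", nTracks = 1L, T = 1e4)
  expect_equal(scalingExponent(fitScaling(lin, range(tgrid))), 1,
               tolerance = 1e-12)

  set.seed(5)
  t50 <- logSpacedGrid(1, 100, 25)[1:50]
  noisy <- new("MSDCurve", times = t50,
               values = 3 * t50^0.6 * exp(stats::rnorm(50, 0, 0.01)),
               averaging = "ensemble", nTracks = 1L, T = 100)
  expect_equal(scalingExponent(fitScaling(noisy, range(t50))), 0.6,
               tolerance = 0.01)

  expect_error(fitScaling(exact, window = c(1, 1.1)), "at least 5")
})

test_that("step-count probabilities normalize and reproduce the MSD", {
  # deterministic unit waits: chi_n(t) concentrates on n = floor(t)
  set.seed(6)
  dets <- lapply(1:50, function(i) ctrwWalk(NULL, model = 1, T = 40, dim = 2))
  times <- c(2.5, 7, 19.9)
  chi <- stepCountProbs(dets, times)
  expect_equal(rowSums(chi), rep(1, 3))
  for (i in seq_along(times))
    expect_equal(unname(chi[i, as.character(floor(times[i]))]), 1)
  msdA <- msdFromStepCounts(dets, NULL, times)
  msdB <- ensembleMSD(dets, times)
  expect_equal(msdValues(msdA), msdValues(msdB), tolerance = 1e-10)

  # heavy-tailed case: the two estimators agree within 3 SE
  model <- waitingTimeModel(0.5)
  set.seed(7)
  trs <- lapply(1:400, function(i) ctrwWalk(NULL, model, T = 1e5, dim = 3))
  tcheck <- c(1e2, 1e3, 1e4, 1e5)
  chi2 <- stepCountProbs(trs, tcheck)
  expect_equal(rowSums(chi2), rep(1, 4))
  direct <- ensembleMSD(trs, tcheck)
  viaChi <- msdFromStepCounts(trs, NULL, tcheck)
  perTrack <- vapply(trs, function(tr) {
    idx <- findInterval(tcheck, eventTimes(tr))
    rowSums((positions(tr)[idx, ] - rep(positions(tr)[1, ], each = 4))^2)
  }, numeric(4))
  se <- apply(perTrack, 1, stats::sd) / sqrt(length(trs))
  expect_true(all(abs(msdValues(viaChi) - msdValues(direct)) < 3 * se))

  expect_error(stepCountProbs(trs, 2e5), "horizon")
})

test_that("ergodic walks agree between time and ensemble averaging", {
  set.seed(8)
  trs <- lapply(1:120, function(i) brownianTrack(3000, dim = 2))
  lagsAt <- c(10, 30, 100)
  taMean <- rowMeans(vapply(trs, function(tr)
    msdValues(timeAveragedMSD(tr, lags = lagsAt)), numeric(3)))
  # the single-window ensemble estimate is noisier: compare within 3 SE
  perTrack <- vapply(trs, function(tr) {
    idx <- findInterval(lagsAt, eventTimes(tr))
    rowSums((positions(tr)[idx, ] - rep(positions(tr)[1, ], each = 3))^2)
  }, numeric(3))
  se <- apply(perTrack, 1, stats::sd) / sqrt(length(trs))
  em <- msdValues(ensembleMSD(trs, lagsAt))
  expect_true(all(abs(taMean - em) < 3 * se))
  # both agree with the closed form MSD(t) = t
  expect_equal(taMean, lagsAt, tolerance = 0.05)
})

test_that("non-ergodic CTRW: per-track exponents scatter, ensemble holds", {
  model <- waitingTimeModel(0.5)
  set.seed(9)
  trs <- lapply(1:200, function(i) ctrwWalk(NULL, model, T = 1e5, dim = 3))
  tgrid <- logSpacedGrid(10, 1e5, 8)
  ensExp <- scalingExponent(fitScaling(ensembleMSD(trs, tgrid),
                                       window = c(10, 1e5)))
  expect_equal(ensExp, 0.5, tolerance = 0.07)
  perTrack <- vapply(trs, function(tr) {
    v <- msdValues(ensembleMSD(list(tr), tgrid))
    if (any(v <= 0)) return(NA_real_)
    scalingExponent(fitScaling(ensembleMSD(list(tr), tgrid),
                               window = c(10, 1e5)))
  }, numeric(1))
  expect_gt(stats::sd(perTrack, na.rm = TRUE), 0.15)
})
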