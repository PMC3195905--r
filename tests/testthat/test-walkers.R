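test_that("inverse-gamma waiting times have the stated law", {
  # density normalizes and has a divergent first moment
  expect_equal(stats::integrate(dWaitingTime, 0, Inf, gamma = 0.7,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  partial <- vapply(c(1e2, 1e4, 1e6), function(up)
    stats::integrate(function(t) t * dWaitingTime(t, 0.5), 1, up)$value,
    numeric(1))
  expect_true(all(diff(partial) > 1))  # partial first moments keep growing

  # gamma = 1: closed-form CDF exp(-1/t), median 1/log(2)
  w <- sampleWaitingTimes(waitingTimeModel(1), 2e5, seed = 11)
  expect_equal(stats::median(w), 1 / log(2), tolerance = 0.02)

  # gamma = 0.5: KS distance against the incomplete-gamma CDF
  w5 <- sampleWaitingTimes(waitingTimeModel(0.5), 2e4, seed = 12)
  ks <- suppressWarnings(stats::ks.test(w5, function(q) pWaitingTime(q, 0.5)))
  expect_gt(ks$p.value, 0.01)

  # survival tail ~ t^-gamma
  tailT <- stats::quantile(w5, c(0.95, 0.999))
  tGrid <- exp(seq(log(tailT[1]), log(tailT[2]), length.out = 20))
  surv <- vapply(tGrid, function(x) mean(w5 > x), numeric(1))
  slope <- stats::coef(stats::lm(log(surv) ~ log(tGrid)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)

  # scale multiplies draws
  a <- sampleWaitingTimes(waitingTimeModel(0.6, scale = 1), 100, seed = 3)
  b <- sampleWaitingTimes(waitingTimeModel(0.6, scale = 2.5), 100, seed = 3)
  expect_equal(b, 2.5 * a)

  expect_error(waitingTimeModel(1.2), "0, 1")
  expect_error(waitingTimeModel(0), "0, 1")
})

test_that("brownian tracks have unbiased unit steps and linear MSD", {
  expect_identical(nrow(positions(brownianTrack(0, dim = 3))), 1L)

  tr <- brownianTrack(6000, dim = 3, seed = 21)
  steps <- diff(positions(tr))
  expect_true(all(rowSums(abs(steps)) == 1))
  dirs <- steps %*% c(1, 10, 100)  # encode the 6 signed directions
  freq <- table(factor(dirs, levels = c(-100, -10, -1, 1, 10, 100)))
  ci <- 3 * sqrt(1 / 6 * 5 / 6 / 6000)
  expect_true(all(abs(freq / 6000 - 1 / 6) < ci))

  # ensemble MSD(n) = n for the free lattice walk
  set.seed(22)
  reps <- replicate(800, sum(positions(brownianTrack(400, dim = 3))[401, ]^2))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 400), 3 * se)
})

test_that("walks are seed-reproducible and differ across seeds", {
  supp <- carpetSupport(4)
  a <- rwfWalk(supp, 500, seed = 5)
  b <- rwfWalk(supp, 500, seed = 5)
  cc <- rwfWalk(supp, 500, seed = 6)
  expect_identical(positions(a), positions(b))
  expect_false(identical(positions(a), positions(cc)))

  model <- waitingTimeModel(0.6)
  x <- ctrwWalk(supp, model, T = 1000, seed = 7)
  y <- ctrwWalk(supp, model, T = 1000, seed = 7)
  expect_identical(eventTimes(x), eventTimes(y))
  expect_identical(positions(x), positions(y))
})

test_that("the blind ant respects accessibility and blocking", {
  # a start whose every neighbor is blocked (or outside the box) stays put
  m <- matrix(TRUE, 3, 3)
  m[2, 1] <- FALSE  # cell (1,0)
  m[1, 2] <- FALSE  # cell (0,1)
  supp <- fractalSupport(generatorMask(m), kmax = 1)
  tr <- rwfWalk(supp, 200, start = c(0, 0), seed = 8)
  expect_true(all(positions(tr) == 0L))

  expect_error(rwfWalk(carpetSupport(1), 10, start = c(1, 1)),
               "not accessible")

  # every visited site of a carpet walk is accessible
  supp6 <- carpetSupport(6)
  tr6 <- rwfWalk(supp6, 5000, seed = 9)
  expect_true(all(isAccessible(unique(positions(tr6)), supp6)))
})

test_that("RWF on the full lattice recovers normal diffusion", {
  supp <- fractalSupport(fullMask(3, 2), kmax = 6)
  set.seed(31)
  trs <- lapply(1:500, function(i) rwfWalk(supp, 3000))
  fit <- fitScaling(ensembleMSD(trs, logSpacedGrid(1, 3000, 10)),
                    window = c(10, 3000))
  expect_equal(scalingExponent(fit), 1, tolerance = 0.05)
})

test_that("CTRW semantics: waiting precedes each step, horizon respected", {
  supp <- fractalSupport(fullMask(3, 2), kmax = 4)
  # deterministic unit waiting times reduce to tick dynamics
  tr <- ctrwWalk(supp, model = 1, T = 50.5, seed = 41)
  expect_identical(eventTimes(tr), as.numeric(0:50))
  set.seed(42)
  dets <- lapply(1:300, function(i) ctrwWalk(NULL, model = 1, T = 300, dim = 3))
  fit <- fitScaling(ensembleMSD(dets, logSpacedGrid(1, 300, 10)),
                    window = c(3, 300))
  expect_equal(scalingExponent(fit), 1, tolerance = 0.05)
  expect_equal(scalingPrefactor(fit), 1, tolerance = 0.15)

  # heavy-tailed waiting: all events inside the horizon, times increasing
  model <- waitingTimeModel(0.5)
  trc <- ctrwWalk(NULL, model, T = 1e4, seed = 43)
  expect_lte(max(eventTimes(trc)), 1e4)
  expect_true(all(diff(eventTimes(trc)) > 0))
  expect_error(ctrwWalk(NULL, model, T = -1), "positive")
})

test_that("LCTRW geometric and occupancy limits", {
  supp <- carpetSupport(6)
  model <- waitingTimeModel(0.5)

  # removing the cap recovers the CTRW bitwise
  a <- ctrwWalk(supp, model, T = 5e3, seed = 51)
  b <- lctrwWalk(supp, model, T = 5e3, seed = 51, rmax = Inf)
  expect_identical(eventTimes(a), eventTimes(b))
  expect_identical(positions(a), positions(b))

  # a one-lattice-unit cap bounds the MSD by ell0^2
  tr1 <- lctrwWalk(NULL, model, T = 5e3, seed = 52, dim = 2, rmax = 1)
  d2 <- rowSums(positions(tr1)^2)
  expect_lte(max(d2), 1)

  # cap rmax = 10: the time-averaged MSD plateaus at or below rmax^2
  set.seed(53)
  trl <- lapply(1:30, function(i) lctrwWalk(supp, model, T = 1e6, rmax = 10))
  taMax <- vapply(trl, function(x)
    max(msdValues(timeAveragedMSD(x))), numeric(1))
  expect_true(all(taMax <= 100 + 1e-9))
  ens <- ensembleMSD(trl, logSpacedGrid(10, 1e6, 10))
  expect_true(all(msdValues(ens) <= 100 + 1e-9))

  # occupancy condition: C >= 1 refuses to simulate
  crowded <- countingConfig(cm = 2e-8, dV = 0.14e-15, tauD = 1e-3, T = 10)
  expect_error(lctrwWalk(supp, model, T = 100, counting = crowded),
               "single-molecule condition")
  sparse <- countingConfig(cm = 1e-9, dV = 0.14e-15, tauD = 1e-3, T = 10)
  trOK <- lctrwWalk(supp, model, T = 100, seed = 54, counting = sparse)
  expect_equal(trOK@meta$C, expectedCount(1e-9, 0.14e-15))
})

test_that("heavy-tailed CTRW breaks ergodicity on the full lattice", {
  model <- waitingTimeModel(0.5)
  set.seed(61)
  trs <- lapply(1:300, function(i) ctrwWalk(NULL, model, T = 1e5, dim = 3))
  fit <- fitScaling(ensembleMSD(trs, logSpacedGrid(1, 1e5, 10)),
                    window = c(10, 1e5))
  expect_equal(scalingExponent(fit), 0.5, tolerance = 0.07)

  # amplitude scatter of per-track time-averaged MSDs stays broad
  amps <- tamsdAmplitudes(trs[1:150], lag = 100)
  expect_gt(stats::sd(amps) / mean(amps), 0.3)
})
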