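test_that("the mixed objective reproduces hand arithmetic and its limits", {
  ## one evaluation point with S = 0.5, S_e = 0.25, alpha = 0.6:
  ## 0.6 * 0.0625 + 0.4 * log(2)^2
  o <- burstKinetics:::.objectiveAL(A = 1, lam = log(0.5), t = 1,
                                    Se = 0.25, alpha = 0.6)
  expect_equal(o, 0.6 * 0.0625 + 0.4 * log(2)^2, tolerance = 1e-12)

  ## alpha = 1 reduces to the linear mean squared error
  t <- 1:5; Se <- exp(-t / 3)
  o1 <- burstKinetics:::.objectiveAL(1, -1/2, t, Se, 1)
  expect_equal(o1, mean((exp(-t / 2) - Se)^2), tolerance = 1e-12)

  ## parameters generating S_e exactly give 0
  expect_equal(burstKinetics:::.objectiveAL(1, -1/3, t, Se, 0.6), 0,
               tolerance = 1e-15)
})

test_that("the objective is invariant to component permutation", {
  s <- kmSurvival(waitingTimeSet(rexp(200, 1/5)))
  p1 <- multiExpParams(c(0.3, 0.7), c(-0.05, -0.2))
  p2 <- multiExpParams(c(0.7, 0.3), c(-0.2, -0.05))
  expect_equal(fitObjective(p1, s), fitObjective(p2, s))
})

test_that("biexponential regression recovers generating parameters", {
  truth <- forwardDistribution(snaModel())
  x <- sampleWaitingTimes(truth, 5e4, seed = 12)
  s <- kmSurvival(waitingTimeSet(x, genotype = "sim"))
  f <- fitMultiExp(s, 2, fitConfig(seed = 5))
  expect_equal(exponents(f@best), exponents(truth), tolerance = 0.1)
  expect_equal(amplitudes(f@best), amplitudes(truth), tolerance = 0.25)
  ## reproducible under the config seed
  f2 <- fitMultiExp(s, 2, fitConfig(seed = 5))
  expect_identical(exponents(f2@best), exponents(f@best))
})

test_that("fitting N=2 to single-exponential data degenerates gracefully", {
  set.seed(14)
  x <- rexp(2e4, 1/9)
  s <- kmSurvival(waitingTimeSet(x))
  f <- fitMultiExp(s, 2, fitConfig(seed = 3))
  lam <- exponents(f@best)
  A <- amplitudes(f@best)
  nested <- min(A) < 0.05 || abs(lam[1] - lam[2]) < 0.2 * abs(lam[2])
  expect_true(nested)
  expect_true(f@accepted)
})

test_that("acceptance tracks the Greenwood band above the cutoff", {
  truth <- forwardDistribution(snaModel())
  x <- sampleWaitingTimes(truth, 5e3, seed = 16)
  s <- kmSurvival(waitingTimeSet(x))
  ## the fitted curve tracks the data and stays inside the band
  f <- fitMultiExp(s, 2, fitConfig(seed = 1))
  expect_true(acceptFit(f, s))
  ## the generating curve stays inside at nearly every grid time (a
  ## pointwise band may exclude it at a few points by construction)
  keep <- s@time >= 10 & s@nRisk >= 30
  S <- multiExpSurvival(truth, s@time[keep])
  inside <- S >= s@lower[keep] & S <= s@upper[keep]
  expect_gt(mean(inside), 0.95)
  ## a grossly wrong curve is rejected
  wrong <- multiExpParams(c(0.5, 0.5), c(-0.001, -1))
  expect_false(acceptFit(wrong, s))
  expect_error(acceptFit(truth, s, ksCutoff = max(s@time) + 1), "cutoff")
})

test_that("state-count selection is parsimonious on two-state data", {
  x <- sampleWaitingTimes(forwardDistribution(snaModel()), 1e4, seed = 18)
  s <- kmSurvival(waitingTimeSet(x))
  f <- selectNumStates(s, fitConfig(seed = 2))
  expect_length(amplitudes(f@best), 2)
  expect_true(f@accepted)
})

test_that("three-state data with separated timescales select N=3", {
  x <- sampleWaitingTimes(forwardDistribution(pauseModel()), 1e4, seed = 19)
  s <- kmSurvival(waitingTimeSet(x))
  f <- selectNumStates(s, fitConfig(seed = 2))
  expect_length(amplitudes(f@best), 3)
  rej <- attr(f, "rejected")
  expect_named(rej, "2")            # the biexponential was tried and failed
})

test_that("the constrained obligatory-pause fit stays on the manifold and is rejected on non-obligatory data", {
  x <- sampleWaitingTimes(forwardDistribution(pauseModel()), 1e4, seed = 20)
  s <- kmSurvival(waitingTimeSet(x))
  f <- fitConstrainedObligatory(s, fitConfig(seed = 2))
  ## constraint residual: sum A_i lambda_i = 0 (forces S'(0) = 0, while
  ## the generating model has S'(0) = -k_ini < 0)
  expect_lt(abs(sum(amplitudes(f@best) * exponents(f@best))), 1e-9)
  expect_false(f@accepted)
  ## its objective cannot beat the unconstrained three-exponential fit
  free <- fitMultiExp(s, 3, fitConfig(seed = 2))
  expect_gte(f@objective, free@objective - 1e-12)
})

test_that("the cutoff KS test separates matching from mismatched models", {
  truth <- forwardDistribution(snaModel())
  x <- sampleWaitingTimes(truth, 1e4, seed = 22)
  wt <- waitingTimeSet(x)
  pGood <- modifiedKsTest(wt, truth, cutoff = 10)
  expect_gt(pGood, 0.01)
  other <- forwardDistribution(promoterModel(1/24, 1/60, 1/18))
  pBad <- modifiedKsTest(wt, other, cutoff = 10)
  expect_lt(pBad, 0.01)
  expect_error(modifiedKsTest(wt, truth, cutoff = max(x) + 1), "30")
  expect_error(modifiedKsTest(waitingTimeSet(rexp(10, 1)), truth, 0.1),
               "30")
})

test_that("error intervals envelope retained solutions and contain the best fit", {
  x <- sampleWaitingTimes(forwardDistribution(snaModel()), 2e4, seed = 24)
  s <- kmSurvival(waitingTimeSet(x))
  f <- fitMultiExp(s, 2, fitConfig(seed = 4))
  iv <- errorIntervals(f, 2)
  best <- c(amplitudes(f@best), exponents(f@best))
  expect_true(all(iv[, "min"] <= best + 1e-12))
  expect_true(all(iv[, "max"] >= best - 1e-12))
  ## a single-solution fit has degenerate intervals
  solo <- new("MultiExpFit", best = f@best, objective = f@objective,
              suboptimal = list(), accepted = TRUE, ksP = NA_real_,
              alpha = 0.6, constrained = FALSE)
  ivSolo <- errorIntervals(solo, 2)
  expect_equal(ivSolo[, "min"], ivSolo[, "max"])
  ## an infinite overflow ratio envelopes every retained local optimum
  ivAll <- errorIntervals(f, 1e12)
  expect_true(all(ivAll[, "min"] <= iv[, "min"] + 1e-12))
  expect_true(all(ivAll[, "max"] >= iv[, "max"] - 1e-12))
})
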