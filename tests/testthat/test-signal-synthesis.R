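test_that("kernel geometry and intensities follow the trapezoid", {
  k <- signalKernel()
  b <- kernelBreaks(k)
  expect_equal(unname(b), c(41/45, 1333/45, 5859/45))
  expect_equal(kernelIntensity(k, 0), 0)
  expect_equal(kernelIntensity(k, 200), 0)  # beyond dwell end ~130.2 s
  expect_equal(kernelIntensity(k, 80), 1)   # plateau
  mid <- (b["rampStart"] + b["rampEnd"]) / 2
  expect_equal(kernelIntensity(k, mid), 0.5, tolerance = 1e-12)
  expect_error(kernelIntensity(k, -1), "non-negative")
  ## closed-form area: half the ramp plus the plateau
  expect_equal(kernelIntegral(k),
               (b[["rampEnd"]] - b[["rampStart"]]) / 2 +
                 (b[["dwellEnd"]] - b[["rampEnd"]]))
})

test_that("convolution superposes kernels and is linear", {
  k <- signalKernel()
  empty <- convolveEvents(initiationEventTrain("n", numeric(0), c(0, 200)), k)
  expect_true(all(intensities(empty) == 0))

  one <- convolveEvents(initiationEventTrain("n", 0, c(0, 300)), k)
  expect_equal(intensities(one), kernelIntensity(k, frameTimes(one)))

  two <- convolveEvents(initiationEventTrain("n", c(20, 30), c(0, 300)), k)
  a <- convolveEvents(initiationEventTrain("n", 20, c(0, 300)), k)
  b <- convolveEvents(initiationEventTrain("n", 30, c(0, 300)), k)
  expect_equal(intensities(two), intensities(a) + intensities(b))
  expect_equal(max(intensities(two)), 2)
})

test_that("total fluorescence equals event count times kernel area", {
  k <- signalKernel()
  ## events well inside the window so no kernel is truncated
  train <- sparseTrain(3, meanGap = 50, tMax = 250, window = c(0, 450))
  trace <- convolveEvents(train, k, frameInterval = 0.5)
  area <- integralAmplitude(trace, tMax = 450)
  expect_equal(area, length(eventTimes(train)) * kernelIntegral(k),
               tolerance = 0.01 * area)
})

test_that("degradation applies noise, clipping and the detection floor", {
  k <- signalKernel()
  tr <- convolveEvents(initiationEventTrain("n", c(5, 10, 15), c(0, 300)), k)
  expect_equal(intensities(degradeTrace(tr, 0, 0)), intensities(tr))

  low <- fluorescenceTrace("n", (0:9) * 3.86, rep(2, 10))
  expect_true(all(intensities(degradeTrace(low, 0, 3)) == 0))

  n1 <- degradeTrace(tr, 0.5, 3, seed = 4)
  n2 <- degradeTrace(tr, 0.5, 3, seed = 4)
  expect_identical(intensities(n1), intensities(n2))
  expect_true(all(intensities(n1) >= 0))
})

test_that("calibration divides by the single-molecule intensity", {
  raw <- fluorescenceTrace("n", (0:4) * 3.86, rep(10, 5), unit = "au")
  cal <- calibrateIntensity(raw, 2)
  expect_equal(intensities(cal), rep(5, 5))
  expect_identical(intensityUnit(cal), "polymerase")
  expect_equal(intensities(calibrateIntensity(raw, 1)), intensities(raw))
  back <- intensities(cal) * 2
  expect_equal(back, intensities(raw), tolerance = 1e-12)
  expect_error(calibrateIntensity(raw, 0), "positive")
})

test_that("cohort generation pairs traces with ground truth and respects limits", {
  m <- snaModel()
  empty <- generateCohort(m, cohortConfig(nNuclei = 0, seed = 1))
  expect_length(empty$traces, 0)

  cfg <- cohortConfig(nNuclei = 4, movieDuration = 600, noiseSd = 0,
                      detectionFloor = 0, gap = gapParams(1, 0, 1e-6),
                      seed = 2)
  co <- generateCohort(m, cfg)
  expect_length(co$traces, 4)
  expect_true(all(co$onsets < 1e-4))  # one-step limit b -> 0 starts at ~0
  ## noiseless, floor-free traces equal the convolution of their truth
  for (i in 1:4) {
    again <- convolveEvents(co$trains[[i]], signalKernel(),
                            frameTimes = frameTimes(co$traces[[i]]))
    expect_equal(intensities(co$traces[[i]]), intensities(again))
  }
  ## determinism under the config seed
  co2 <- generateCohort(m, cfg)
  expect_identical(eventTimes(co2$trains[[3]]), eventTimes(co$trains[[3]]))
})

test_that("trace CSV round trip preserves traces", {
  co <- generateCohort(snaModel(),
                       cohortConfig(nNuclei = 2, movieDuration = 300,
                                    seed = 5))
  f <- tempfile(fileext = ".csv")
  writeTraces(co$traces, f)
  back <- readTraces(f)
  id <- nucleusId(co$traces[[1]])
  expect_equal(intensities(back[[id]]), intensities(co$traces[[1]]))
  expect_equal(frameTimes(back[[id]]), frameTimes(co$traces[[1]]))
})

test_that("onset detection requires consecutive frames above the floor", {
  t <- (0:9) * 3.86
  y <- c(0, 0, 5, 0, 4, 5, 6, 0, 0, 0)
  tr <- fluorescenceTrace("n", t, y)
  expect_equal(detectOnset(tr, 3, minFrames = 2), t[5])
  expect_equal(detectOnset(tr, 3, minFrames = 1), t[3])
  expect_true(is.na(detectOnset(fluorescenceTrace("n", t, rep(0, 10)), 3)))
})
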