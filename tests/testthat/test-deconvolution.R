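test_that("the position grid discretizes at 30 bp resolution", {
  g <- makeGrid(c(0, 35 * 60))
  expect_identical(g@nPositions, 3150L)
  expect_equal(g@stepS, 2/3)
  expect_identical(makeGrid(c(0, 60))@nPositions, 90L)
  expect_identical(makeGrid(c(0, 2/3))@nPositions, 1L)
  expect_error(makeGrid(c(0, 100), stepBp = 0), "positive")
  expect_error(makeGrid(c(10, 10)), "positive")
})

test_that("an all-zero trace deconvolves to an empty train", {
  tr <- fluorescenceTrace("n", (0:50) * 3.86, rep(0, 51))
  out <- deconvolveTrace(tr, signalKernel(), makeGrid(c(0, 200)))
  expect_length(eventTimes(out), 0)
  expect_equal(attr(out, "residual"), 0)
})

test_that("uncalibrated traces are refused", {
  tr <- fluorescenceTrace("n", (0:50) * 3.86, rep(1, 51), unit = "au")
  expect_error(deconvolveTrace(tr, signalKernel(), makeGrid(c(0, 200))),
               "calibrated")
})

test_that("a single on-grid event is recovered exactly", {
  k <- signalKernel()
  train <- initiationEventTrain("n", 20, c(0, 300))
  trace <- convolveEvents(train, k)
  out <- deconvolveTrace(trace, k, makeGrid(c(0, 300)), gaConfig(seed = 1))
  expect_equal(eventTimes(out), 20)
  expect_lt(attr(out, "residual"), 1e-9)
})

test_that("two separated events match the exhaustive two-event oracle", {
  k <- signalKernel()
  truth <- c(30, 90)
  train <- initiationEventTrain("n", truth, c(0, 240))
  trace <- convolveEvents(train, k)
  grid <- makeGrid(c(0, 240))
  out <- deconvolveTrace(trace, k, grid, gaConfig(seed = 2))

  ## oracle: exhaustive search over all <= 2-event placements
  K <- burstKinetics:::kernelResponseMatrix(k, frameTimes(trace),
                                            gridTimes(grid))
  y <- intensities(trace)
  G <- drop(crossprod(K, y))
  csq <- colSums(K^2)
  C <- crossprod(K)
  ssr1 <- -2 * G + csq                       # single-event SSR - ||y||^2
  ssr2 <- outer(ssr1, ssr1, "+") + 2 * C     # pairs (i, j), i != j
  diag(ssr2) <- Inf
  bestPair <- arrayInd(which.min(ssr2), dim(ssr2))
  oracleTimes <- sort(gridTimes(grid)[bestPair])
  expect_true(min(ssr2) < min(ssr1))         # two events beat one
  expect_equal(eventTimes(out), oracleTimes)
  expect_true(all(abs(eventTimes(out) - truth) <= 2/3 + 1e-9))
})

test_that("deconvolution is deterministic under a fixed seed", {
  k <- signalKernel()
  train <- sparseTrain(9, meanGap = 40)
  trace <- convolveEvents(train, k)
  a <- deconvolveTrace(trace, k, makeGrid(c(0, 400)), gaConfig(seed = 7))
  b <- deconvolveTrace(trace, k, makeGrid(c(0, 400)), gaConfig(seed = 7))
  expect_identical(eventTimes(a), eventTimes(b))
})

test_that("longer searches never end with a larger residual", {
  k <- signalKernel()
  train <- sparseTrain(4, meanGap = 25)
  trace <- convolveEvents(train, k)
  grid <- makeGrid(c(0, 400))
  short <- deconvolveTrace(trace, k, grid,
                           gaConfig(nGenerations = 1, localSweeps = 0,
                                    seed = 3))
  long <- deconvolveTrace(trace, k, grid, gaConfig(seed = 3))
  expect_lte(attr(long, "residual"), attr(short, "residual") + 1e-12)
})

test_that("noiseless grid-aligned trains are recovered to grid precision", {
  k <- signalKernel()
  for (seed in 1:8) {
    train <- sparseTrain(seed, meanGap = 60, onGrid = TRUE)
    trace <- convolveEvents(train, k)
    out <- deconvolveTrace(trace, k, makeGrid(c(0, 400)),
                           gaConfig(seed = seed))
    expect_length(eventTimes(out), length(eventTimes(train)))
    if (length(eventTimes(train)))
      expect_true(all(abs(eventTimes(out) - eventTimes(train)) <=
                        2/3 + 1e-9))
  }
})

test_that("off-grid trains still give exact event counts", {
  k <- signalKernel()
  for (seed in 11:15) {
    train <- sparseTrain(seed, meanGap = 60)
    trace <- convolveEvents(train, k)
    out <- deconvolveTrace(trace, k, makeGrid(c(0, 400)),
                           gaConfig(seed = seed))
    expect_length(eventTimes(out), length(eventTimes(train)))
  }
})

test_that("moderate noise degrades dense-trace event counts by at most 10%", {
  k <- signalKernel()
  m <- snaModel()
  n0 <- nN <- 0
  for (i in 1:3) {
    tr <- simulateEventTrain(m, 400, seed = i)
    ev <- eventTimes(tr)
    repeat {
      keep <- c(TRUE, diff(ev) >= 4/3)
      if (all(keep)) break
      ev <- ev[keep]
    }
    train <- initiationEventTrain("n", ev, c(0, 400))
    trace <- convolveEvents(train, k)
    noisy <- degradeTrace(trace, noiseSd = 0.25, detectionFloor = 0,
                          seed = 50 + i)
    grid <- makeGrid(c(0, 400))
    n0 <- n0 + length(eventTimes(deconvolveTrace(trace, k, grid,
                                                 gaConfig(seed = i))))
    nN <- nN + length(eventTimes(deconvolveTrace(noisy, k, grid,
                                                 gaConfig(seed = i))))
  }
  expect_lte(abs(nN - n0) / n0, 0.10)
})

test_that("binned event counts match hand counting and Poisson means", {
  t1 <- initiationEventTrain("a", c(31), c(0, 90))
  t2 <- initiationEventTrain("b", numeric(0), c(0, 90))
  m <- binEvents(list(t2, t1), binWidth = 30)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(rownames(m), c("a", "b"))
  expect_equal(unname(m["a", ]), c(0, 1, 0))
  expect_true(all(m["b", ] == 0))

  set.seed(8)
  ev <- cumsum(rexp(400, 1/9))
  ev <- ev[ev < 3000]
  mm <- binEvents(list(initiationEventTrain("p", ev, c(0, 3000))),
                  binWidth = 30)
  expect_equal(mean(mm), 30/9, tolerance = 0.15)
})

test_that("reconstructSignal shares the convolution contract", {
  k <- signalKernel()
  train <- initiationEventTrain("n", c(10, 50), c(0, 300))
  ft <- seq(0, 300, by = 3.86)
  expect_equal(intensities(reconstructSignal(train, k, ft)),
               intensities(convolveEvents(train, k, frameTimes = ft)))
})
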