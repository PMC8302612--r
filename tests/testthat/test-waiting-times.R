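test_that("the stable window is bounded by the 1/5-max threshold", {
  t <- (0:7) * 3.86
  tr <- fluorescenceTrace("n", t, c(0, 0, 5, 9, 10, 4, 1, 0))
  w <- windowTrace(tr)            # max 10, threshold 2, frames 3..6 qualify
  expect_equal(w, c(t[3], t[6]))

  flat <- fluorescenceTrace("n", t, rep(4, 8))
  expect_equal(windowTrace(flat), c(t[1], t[8]))

  single <- fluorescenceTrace("n", t, c(0, 0, 0, 8, 0, 0, 0, 0))
  expect_equal(windowTrace(single), c(t[4], t[4]))

  expect_null(windowTrace(fluorescenceTrace("n", t, rep(0, 8))))
})

test_that("waiting times are successive differences plus a censored tail", {
  tr <- initiationEventTrain("n", c(10, 19, 31), c(0, 40))
  wt <- extractWaitingTimes(tr)
  expect_equal(wt@deltaT, c(9, 12, 9))
  expect_equal(wt@censored, c(FALSE, FALSE, TRUE))

  one <- extractWaitingTimes(initiationEventTrain("n", 10, c(0, 40)))
  expect_equal(one@deltaT, 30)
  expect_true(one@censored)

  none <- extractWaitingTimes(initiationEventTrain("n", numeric(0),
                                                   c(0, 40)))
  expect_length(none@deltaT, 0)

  noCens <- extractWaitingTimes(tr, censorFinal = FALSE)
  expect_equal(noCens@deltaT, c(9, 12))
  expect_false(any(noCens@censored))
})

test_that("a train inside the window yields n-1 observed and 1 censored", {
  set.seed(21)
  for (i in 1:10) {
    tr <- simulateEventTrain(snaModel(), 400)
    n <- length(eventTimes(tr))
    if (n < 2) next
    wt <- extractWaitingTimes(tr)
    expect_equal(sum(!wt@censored), n - 1)
    expect_equal(sum(wt@censored), as.integer(max(eventTimes(tr)) < 400))
  }
})

test_that("pooling concatenates one genotype and is order-invariant", {
  a <- waitingTimeSet(c(1, 2), genotype = "g1", nucleusId = c("a", "a"))
  b <- waitingTimeSet(c(3), censored = TRUE, genotype = "g1",
                      nucleusId = "b")
  ab <- poolGenotype(list(a, b))
  ba <- poolGenotype(list(b, a))
  expect_length(ab@deltaT, 3)
  expect_equal(sort(ab@deltaT), sort(ba@deltaT))
  expect_equal(sum(ab@censored), 1)
  expect_length(poolGenotype(list())@deltaT, 0)
  wrong <- waitingTimeSet(1, genotype = "g2")
  expect_error(poolGenotype(list(a, wrong)), "mixed genotypes")
})

test_that("the product-limit estimator matches textbook hand cases", {
  s <- kmSurvival(waitingTimeSet(c(1, 2, 3)))
  expect_equal(s@time, c(0, 1, 2, 3))
  expect_equal(s@surv, c(1, 2/3, 1/3, 0))

  ## censoring at 2: S(1) = 2/3, then the last subject fails at 3
  s2 <- kmSurvival(waitingTimeSet(c(1, 2, 3), censored = c(FALSE, TRUE,
                                                           FALSE)))
  expect_equal(s2@surv[s2@time == 1], 2/3)
  expect_equal(s2@surv[s2@time == 3], 0)

  expect_error(kmSurvival(waitingTimeSet(c(1, 2), censored = c(TRUE, TRUE))),
               "censored")
})

test_that("without censoring the estimator equals the empirical survival", {
  set.seed(31)
  x <- rexp(500, 1/9)
  s <- kmSurvival(waitingTimeSet(x))
  emp <- vapply(s@time, function(t) mean(x > t), numeric(1))
  expect_equal(s@surv, emp, tolerance = 1e-12)
  expect_true(all(diff(s@surv) <= 1e-12))
  expect_true(all(s@lower <= s@surv + 1e-9 & s@surv <= s@upper + 1e-9))
})

test_that("integral amplitude is the trapezoidal area over 30 min", {
  t <- seq(0, 100, by = 1)
  expect_equal(integralAmplitude(fluorescenceTrace("n", t, rep(0, 101))), 0)
  expect_equal(integralAmplitude(fluorescenceTrace("n", t, rep(2, 101))),
               200)
  one <- convolveEvents(initiationEventTrain("n", 0, c(0, 400)),
                        signalKernel(), frameInterval = 0.25)
  expect_equal(integralAmplitude(one), kernelIntegral(signalKernel()),
               tolerance = 0.3)
})

test_that("activation statistics report the cumulative curve and t50", {
  all10 <- activationStats(rep(600, 20), 20)
  expect_equal(all10$t50, 600)
  half <- activationStats(c(rep(300, 10), rep(NA, 10)), 20)
  expect_equal(half$t50, 300)
  low <- activationStats(c(rep(100, 8), rep(NA, 12)), 20)
  expect_true(is.na(low$t50))
  expect_error(activationStats(numeric(0), 0), "positive")
})

test_that("pooled simulated waiting times match the renewal mean", {
  m <- snaModel()
  d <- derivedKinetics(m)
  sets <- lapply(1:20, function(i) {
    tr <- simulateEventTrain(m, 3000, seed = 40 + i)
    extractWaitingTimes(tr, censorFinal = FALSE, genotype = "sna")
  })
  pooled <- poolGenotype(sets)
  expected <- 1 / (d@pOn * m@kIni)   # renewal-reward mean interval
  expect_equal(mean(pooled@deltaT), expected, tolerance = 0.05 * expected)
})
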