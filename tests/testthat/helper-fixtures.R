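## Shared fixtures: models in the regimes the package targets and
## small train/trace builders. Everything is generated in code.

snaModel <- function() promoterModel(k1Plus = 1/24, k1Minus = 1/242,
                                     kIni = 1/9)

pauseModel <- function() promoterModel(1/30, 1/90, 1/9,
                                       k2Plus = 1/400, k2Minus = 1/80)

randomTwoState <- function() {
  r <- exp(stats::runif(3, log(1e-3), log(0.5)))
  promoterModel(r[1], r[2], r[3])
}

randomThreeState <- function() {
  r <- exp(stats::runif(5, log(1e-3), log(0.5)))
  promoterModel(r[1], r[2], r[3], r[4], r[5])
}

## Poisson train with a minimum-spacing filter (and optional snapping
## to the deconvolution grid), inside a window with an edge margin so
## every kernel is substantially observed.
sparseTrain <- function(seed, meanGap = 60, tMax = 350, window = c(0, 400),
                        onGrid = FALSE, step = 2/3) {
  set.seed(seed)
  ev <- cumsum(stats::rexp(50, 1 / meanGap))
  ev <- ev[ev < tMax]
  if (onGrid) ev <- unique(round(ev / step) * step)
  repeat {
    keep <- c(TRUE, diff(ev) >= 2 * step - 1e-9)
    if (all(keep)) break
    ev <- ev[keep]
  }
  initiationEventTrain(paste0("n", seed), ev, window)
}

## canonical 3-state rate ordering (PAUSE is the longer-lived
## inactive state), for comparing against inversion output
canonicalRates <- function(model) {
  r <- kineticRates(model)
  if (model@nStates == 3L && r[["k2_plus"]] > r[["k1_plus"]]) {
    r[c("k1_plus", "k1_minus", "k2_plus", "k2_minus")] <-
      r[c("k2_plus", "k2_minus", "k1_plus", "k1_minus")]
  }
  r
}
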