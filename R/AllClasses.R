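#' @import methods
NULL

## Central S4 classes. State ordering is fixed throughout as
## (OFF, ON) for two-state models and (OFF, ON, PAUSE) for three-state
## models; initiation occurs only in ON.

#' Markov promoter model
#'
#' A two- or three-state promoter-state Markov chain with Poisson
#' initiation from the ON state. The two-state (telegraph) model has
#' rates \code{k1Plus} (OFF to ON), \code{k1Minus} (ON to OFF) and
#' \code{kIni} (initiation while ON). The three-state non-obligatory
#' pause model adds a second inactive state reachable only from ON:
#' \code{k2Minus} (ON to PAUSE) and \code{k2Plus} (PAUSE to ON).
#'
#' @slot nStates integer, 2 or 3.
#' @slot k1Plus,k1Minus,kIni numeric rates in 1/s, strictly positive.
#' @slot k2Plus,k2Minus numeric rates in 1/s for the three-state model;
#'   \code{NA} for two-state models.
#' @seealso [promoterModel()], [forwardDistribution()],
#'   [simulateEventTrain()], [derivedKinetics()]
#' @export
setClass("PromoterModel",
  representation(nStates = "integer",
                 k1Plus = "numeric", k1Minus = "numeric", kIni = "numeric",
                 k2Plus = "numeric", k2Minus = "numeric"))

setValidity("PromoterModel", function(object) {
  msg <- character()
  if (!object@nStates %in% c(2L, 3L))
    msg <- c(msg, "nStates must be 2 or 3")
  core <- c(k1Plus = object@k1Plus, k1Minus = object@k1Minus,
            kIni = object@kIni)
  for (nm in names(core)) {
    v <- core[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("rate '%s' must be a single positive finite number", nm))
  }
  if (object@nStates == 3L) {
    pause <- c(k2Plus = object@k2Plus, k2Minus = object@k2Minus)
    for (nm in names(pause)) {
      v <- pause[[nm]]
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("rate '%s' must be a single positive finite number", nm))
    }
  } else {
    if (!all(is.na(c(object@k2Plus, object@k2Minus))))
      msg <- c(msg, "pause rates must be absent (NA) for a 2-state model")
  }
  if (length(msg)) msg else TRUE
})

#' Multiexponential survival parameters
#'
#' Amplitudes and exponents of an inter-initiation waiting-time survival
#' function S(t) = sum_i A_i exp(lambda_i t). Amplitudes sum to one;
#' exponents are stored as negative reals sorted descending (the
#' slowest-decaying component first).
#'
#' @slot amplitudes numeric vector A_1..A_N, sum = 1.
#' @slot exponents numeric vector lambda_1..lambda_N in 1/s, all < 0,
#'   pairwise distinct, sorted descending.
#' @seealso [multiExpParams()], [multiExpSurvival()], [momentSums()]
#' @export
setClass("MultiExpParams",
  representation(amplitudes = "numeric", exponents = "numeric"))

setValidity("MultiExpParams", function(object) {
  A <- object@amplitudes; lam <- object@exponents
  msg <- character()
  if (length(A) != length(lam) || length(A) < 1L)
    msg <- c(msg, "amplitudes and exponents must have equal positive length")
  if (abs(sum(A) - 1) > 1e-9)
    msg <- c(msg, "amplitudes must sum to 1 (tolerance 1e-9)")
  if (any(!is.finite(lam)) || any(lam >= 0))
    msg <- c(msg, "all exponents must be finite and negative")
  if (length(lam) > 1L && any(diff(lam) > 0))
    msg <- c(msg, "exponents must be sorted descending (dominant timescale first)")
  if (length(lam) > 1L) {
    d <- abs(outer(lam, lam, "-"))
    diag(d) <- Inf
    if (min(d) < 1e-10 * max(abs(lam)))
      msg <- c(msg, "exponents are degenerate (repeated eigenvalues)")
  }
  if (length(msg)) msg else TRUE
})

#' Train of Pol II initiation events for one nucleus
#'
#' @slot nucleusId character scalar.
#' @slot times numeric, strictly increasing event times in seconds from
#'   the window start.
#' @slot window numeric length-2, observation window (t_start, t_end).
#' @seealso [initiationEventTrain()], [simulateEventTrain()],
#'   [deconvolveTrace()]
#' @export
setClass("InitiationEventTrain",
  representation(nucleusId = "character", times = "numeric",
                 window = "numeric"))

setValidity("InitiationEventTrain", function(object) {
  msg <- character()
  if (length(object@window) != 2L || object@window[2] < object@window[1])
    msg <- c(msg, "window must be (t_start, t_end) with t_end >= t_start")
  t <- object@times
  if (length(t)) {
    if (any(diff(t) <= 0)) msg <- c(msg, "event times must be strictly increasing")
    if (min(t) < object@window[1] || max(t) > object@window[2])
      msg <- c(msg, "event times must lie within the window")
  }
  if (length(msg)) msg else TRUE
})

#' Frame-sampled fluorescence trace of one transcription site
#'
#' @slot nucleusId character scalar.
#' @slot time numeric, uniform frame grid in seconds.
#' @slot intensity numeric, non-negative; polymerase units when
#'   \code{unit == "polymerase"}, arbitrary units when \code{unit == "au"}.
#' @slot unit character, "polymerase" or "au".
#' @slot genotype,movie character tags.
#' @seealso [fluorescenceTrace()], [convolveEvents()], [windowTrace()]
#' @export
setClass("FluorescenceTrace",
  representation(nucleusId = "character", time = "numeric",
                 intensity = "numeric", unit = "character",
                 genotype = "character", movie = "character"))

setValidity("FluorescenceTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@intensity))
    msg <- c(msg, "time and intensity must have equal length")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (max(dt) - min(dt) > 1e-6)
      msg <- c(msg, "frame times must be uniformly spaced (tolerance 1e-6 s)")
  }
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@unit %in% c("polymerase", "au"))
    msg <- c(msg, "unit must be 'polymerase' or 'au'")
  if (length(msg)) msg else TRUE
})

#' Single-polymerase signal kernel
#'
#' Fluorescence contributed by one polymerase as a function of time since
#' initiation: zero until the polymerase reaches the MS2 cassette, a
#' linear ramp while the stem loops are transcribed, a plateau until the
#' polymerase leaves the transcription unit, plus an optional retention
#' time at the site.
#'
#' @slot preLen,ms2Len,postLen numeric lengths in bp of the pre-MS2
#'   fragment, the MS2 cassette and the post-MS2 fragment.
#' @slot speed numeric elongation speed in bp/s.
#' @slot retention numeric retention time at the site in s.
#' @seealso [signalKernel()], [kernelIntensity()], [kernelIntegral()]
#' @export
setClass("SignalKernel",
  representation(preLen = "numeric", ms2Len = "numeric", postLen = "numeric",
                 speed = "numeric", retention = "numeric"))

setValidity("SignalKernel", function(object) {
  msg <- character()
  if (any(c(object@preLen, object@ms2Len, object@postLen, object@speed) <= 0))
    msg <- c(msg, "lengths and elongation speed must be positive")
  if (object@retention < 0)
    msg <- c(msg, "retention time must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Discrete grid of candidate polymerase initiation positions
#'
#' @slot stepBp numeric grid step in bp.
#' @slot stepS numeric grid step in s (stepBp / elongation speed).
#' @slot window numeric length-2 time window in s.
#' @slot nPositions integer, ceiling(window length / stepS).
#' @seealso [makeGrid()], [deconvolveTrace()]
#' @export
setClass("PositionGrid",
  representation(stepBp = "numeric", stepS = "numeric",
                 window = "numeric", nPositions = "integer"))

setValidity("PositionGrid", function(object) {
  msg <- character()
  if (object@stepBp <= 0 || object@stepS <= 0)
    msg <- c(msg, "grid step must be positive")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must have positive length")
  n <- ceiling(diff(object@window) / object@stepS - 1e-9)
  if (object@nPositions != as.integer(n))
    msg <- c(msg, "nPositions must equal ceiling(window length / stepS)")
  if (length(msg)) msg else TRUE
})

#' Set of inter-initiation waiting times
#'
#' Observed waiting times between successive Pol II initiation events,
#' with right-censoring flags for final open intervals.
#'
#' @slot deltaT numeric waiting times in s, all > 0.
#' @slot censored logical, same length as \code{deltaT}.
#' @slot genotype character scalar tag.
#' @slot nucleusId character, source nucleus per waiting time.
#' @seealso [extractWaitingTimes()], [poolGenotype()], [kmSurvival()]
#' @export
setClass("WaitingTimeSet",
  representation(deltaT = "numeric", censored = "logical",
                 genotype = "character", nucleusId = "character"))

setValidity("WaitingTimeSet", function(object) {
  msg <- character()
  n <- length(object@deltaT)
  if (length(object@censored) != n || length(object@nucleusId) != n)
    msg <- c(msg, "censored flags and nucleus ids must match deltaT length")
  if (any(object@deltaT <= 0)) msg <- c(msg, "waiting times must be positive")
  if (length(object@genotype) != 1L) msg <- c(msg, "genotype must be a scalar tag")
  if (length(msg)) msg else TRUE
})

#' Nonparametric survival estimate
#'
#' Product-limit (Kaplan-Meier) estimate of the waiting-time survival
#' function with pointwise 95% Greenwood confidence bounds.
#'
#' @slot time numeric grid in s (includes t = 0).
#' @slot surv numeric survival values, non-increasing, surv[1] = 1.
#' @slot lower,upper numeric 95% confidence bounds in [0, 1].
#' @slot nRisk,nEvent numeric per-time counts.
#' @seealso [kmSurvival()], [fitMultiExp()], [acceptFit()]
#' @export
setClass("SurvivalEstimate",
  representation(time = "numeric", surv = "numeric",
                 lower = "numeric", upper = "numeric",
                 nRisk = "numeric", nEvent = "numeric"))

setValidity("SurvivalEstimate", function(object) {
  msg <- character()
  n <- length(object@time)
  if (any(lengths(list(object@surv, object@lower, object@upper,
                       object@nRisk, object@nEvent)) != n))
    msg <- c(msg, "all fields must share the time grid length")
  if (n && abs(object@surv[1] - 1) > 1e-12)
    msg <- c(msg, "survival must start at 1")
  if (any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  ok <- object@lower <= object@surv + 1e-9 & object@surv <= object@upper + 1e-9 &
    object@lower >= -1e-9 & object@upper <= 1 + 1e-9
  if (any(!ok)) msg <- c(msg, "bounds must satisfy 0 <= lower <= surv <= upper <= 1")
  if (length(msg)) msg else TRUE
})

#' Multiexponential regression fit
#'
#' Best multiexponential fit to a nonparametric survival estimate, the
#' retained suboptimal local optima, and fit diagnostics.
#'
#' @slot best [MultiExpParams-class] of the best local optimum.
#' @slot objective numeric value of the mixed linear/log objective.
#' @slot suboptimal list of \code{list(params=, objective=)} for retained
#'   local optima (objective >= best).
#' @slot accepted logical, whether the parametric curve stays inside the
#'   Greenwood band (evaluated above the short-time cutoff).
#' @slot ksP numeric, cutoff KS p-value (NA when not computed).
#' @slot alpha numeric weight of the linear-scale term.
#' @slot constrained logical, TRUE for the obligatory-pause constrained fit.
#' @seealso [fitMultiExp()], [selectNumStates()], [errorIntervals()]
#' @export
setClass("MultiExpFit",
  representation(best = "MultiExpParams", objective = "numeric",
                 suboptimal = "list", accepted = "logical",
                 ksP = "numeric", alpha = "numeric", constrained = "logical"))

#' Kinetic rates recovered by model inversion
#'
#' @slot nStates integer, 2 or 3.
#' @slot rates named numeric: k1_plus, k1_minus, k_ini and, for 3-state,
#'   k2_plus, k2_minus (1/s).
#' @slot valid logical, FALSE when the inverse problem is ill-posed for
#'   the input parameters (non-positive rates, vanishing denominators or a
#'   negative discriminant).
#' @slot reason character, diagnostic when invalid.
#' @slot intervals numeric matrix (rates x c(min, max)) or empty; filled
#'   by [kineticsReport()].
#' @seealso [invertTwoState()], [invertThreeState()], [kineticsReport()]
#' @export
setClass("KineticRates",
  representation(nStates = "integer", rates = "numeric", valid = "logical",
                 reason = "character", intervals = "matrix"))

#' Derived steady-state kinetics
#'
#' Mean state durations, steady-state occupancy probabilities and burst
#' size implied by a promoter model.
#'
#' @slot tOn,tOff,tPause numeric durations in s (tPause is NA for 2-state).
#' @slot pOn,pOff,pPause numeric probabilities summing to 1 (pPause NA for
#'   2-state models, where pOn + pOff = 1).
#' @slot burstSize numeric; transcripts per ON period, k_ini/k_off for the
#'   2-state model. For 3-state models the analogous ON-exit composite
#'   k_ini/(k1_minus + k2_minus) is reported.
#' @seealso [derivedKinetics()]
#' @export
setClass("DerivedKinetics",
  representation(tOn = "numeric", tOff = "numeric", tPause = "numeric",
                 pOn = "numeric", pOff = "numeric", pPause = "numeric",
                 burstSize = "numeric"))

setValidity("DerivedKinetics", function(object) {
  p <- c(object@pOn, object@pOff, object@pPause)
  p <- p[!is.na(p)]
  msg <- character()
  if (any(p < -1e-12)) msg <- c(msg, "probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) msg <- c(msg, "probabilities must sum to 1")
  d <- c(object@tOn, object@tOff, object@tPause)
  if (any(d[!is.na(d)] <= 0)) msg <- c(msg, "durations must be positive")
  if (length(msg)) msg else TRUE
})

#' Mixed-gamma postmitotic gap parameters
#'
#' The delay between mitosis and the first initiation event is modeled as
#' a mixture of Erlang distributions with one, two or three rate-limiting
#' steps of common mean duration \code{b}.
#'
#' @slot p1,p2 numeric mixture probabilities of one and two steps
#'   (three-step weight is 1 - p1 - p2).
#' @slot b numeric mean step duration in s.
#' @seealso [gapParams()], [gapSurvival()], [sampleGap()], [fitGap()]
#' @export
setClass("GapParams",
  representation(p1 = "numeric", p2 = "numeric", b = "numeric"))

setValidity("GapParams", function(object) {
  msg <- character()
  if (object@p1 < 0 || object@p2 < 0 || object@p1 + object@p2 > 1 + 1e-12)
    msg <- c(msg, "mixture probabilities must satisfy p1, p2 >= 0 and p1 + p2 <= 1")
  if (!is.finite(object@b) || object@b <= 0)
    msg <- c(msg, "mean step duration b must be positive")
  if (length(msg)) msg else TRUE
})
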