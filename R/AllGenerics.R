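#' Exact waiting-time distribution of a promoter model
#'
#' Computes the amplitudes and exponents of the inter-initiation
#' waiting-time survival function implied by a promoter model, as the
#' interval distribution of the Markov-modulated Poisson process started
#' in the ON state (the post-event state). With generator Q and diagonal
#' initiation-rate matrix R, S(t) = <ON| exp((Q - R) t) |1>; the
#' exponents are the eigenvalues of Q - R and the amplitudes follow from
#' its spectral decomposition.
#'
#' @param model a [PromoterModel-class].
#' @return a [MultiExpParams-class] with N = nStates components.
#' @examples
#' m <- promoterModel(k1Plus = 1/24, k1Minus = 1/242, kIni = 1/9)
#' p <- forwardDistribution(m)
#' sum(amplitudes(p) * exponents(p))  # equals -kIni
#' @export
setGeneric("forwardDistribution",
           function(model) standardGeneric("forwardDistribution"))

#' Simulate a train of initiation events (Gillespie)
#'
#' Exact stochastic simulation of the promoter-state chain with Poisson
#' initiation from the ON state. The chain starts in its steady-state
#' distribution unless \code{startState} is given.
#'
#' @param model a [PromoterModel-class].
#' @param duration observation window length in s (window is (0, duration)).
#' @param seed optional integer seed for reproducibility.
#' @param nucleusId identifier for the resulting train.
#' @param startState optional state name ("OFF", "ON", "PAUSE"); default
#'   samples the steady state.
#' @return an [InitiationEventTrain-class].
#' @export
setGeneric("simulateEventTrain",
           function(model, duration, seed = NULL, nucleusId = "sim",
                    startState = NULL)
             standardGeneric("simulateEventTrain"))

#' Steady-state kinetics derived from a promoter model
#'
#' Mean state durations (T_OFF = 1/k1_plus; T_ON = 1/k1_minus for the
#' 2-state model, 1/(k1_minus + k2_minus) for 3-state; T_PAUSE =
#' 1/k2_plus), stationary occupancy probabilities and burst size.
#'
#' @param model a [PromoterModel-class].
#' @return a [DerivedKinetics-class].
#' @examples
#' derivedKinetics(promoterModel(k1Plus = 1/24, k1Minus = 1/242, kIni = 1/9))
#' @export
setGeneric("derivedKinetics",
           function(model) standardGeneric("derivedKinetics"))

#' Symmetric-function moment sums of a multiexponential distribution
#'
#' Amplitude-weighted power sums S_k = sum_i A_i lambda_i^k for
#' k = 1, 2, 3 and, for three-component distributions, the symmetric
#' functions of the exponents L1 = sum lambda_i, L2 = sum_{i<j}
#' lambda_i lambda_j and L3 = lambda_1 lambda_2 lambda_3 used by the
#' closed-form model inversion.
#'
#' @param params a [MultiExpParams-class].
#' @return named list with S1, S2, S3 and, for N = 3, L1, L2, L3.
#' @export
setGeneric("momentSums", function(params) standardGeneric("momentSums"))

## Accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("exponents", function(x) standardGeneric("exponents"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("nucleusId", function(x) standardGeneric("nucleusId"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("intensityUnit", function(x) standardGeneric("intensityUnit"))
#' @rdname accessors
#' @export
setGeneric("kineticRates", function(x) standardGeneric("kineticRates"))

#' Accessors for burstKinetics objects
#'
#' @param x an object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("amplitudes", "MultiExpParams", function(x) x@amplitudes)
#' @rdname accessors
#' @export
setMethod("exponents", "MultiExpParams", function(x) x@exponents)
#' @rdname accessors
#' @export
setMethod("eventTimes", "InitiationEventTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("nucleusId", "InitiationEventTrain", function(x) x@nucleusId)
#' @rdname accessors
#' @export
setMethod("nucleusId", "FluorescenceTrace", function(x) x@nucleusId)
#' @rdname accessors
#' @export
setMethod("frameTimes", "FluorescenceTrace", function(x) x@time)
#' @rdname accessors
#' @export
setMethod("intensities", "FluorescenceTrace", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("intensityUnit", "FluorescenceTrace", function(x) x@unit)
#' @rdname accessors
#' @export
setMethod("kineticRates", "KineticRates", function(x) x@rates)
#' @rdname accessors
#' @export
setMethod("kineticRates", "PromoterModel", function(x) {
  r <- c(k1_plus = x@k1Plus, k1_minus = x@k1Minus, k_ini = x@kIni)
  if (x@nStates == 3L)
    r <- c(r, k2_plus = x@k2Plus, k2_minus = x@k2Minus)
  r
})
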