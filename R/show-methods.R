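#' @describeIn PromoterModel-class compact display
#' @param object a \code{PromoterModel}.
#' @export
setMethod("show", "PromoterModel", function(object) {
  cat(sprintf("%d-state promoter model\n", object@nStates))
  r <- kineticRates(object)
  cat(sprintf("  %-9s %.6g /s  (mean %.3g s)\n", names(r), r, 1 / r),
      sep = "")
})

#' @describeIn MultiExpParams-class compact display
#' @param object a \code{MultiExpParams}.
#' @export
setMethod("show", "MultiExpParams", function(object) {
  n <- length(object@amplitudes)
  cat(sprintf("%d-exponential survival parameters\n", n))
  for (i in seq_len(n))
    cat(sprintf("  A%d = %.4g, lambda%d = %.6g /s (timescale %.3g s)\n",
                i, object@amplitudes[i], i, object@exponents[i],
                -1 / object@exponents[i]))
})

#' @describeIn InitiationEventTrain-class compact display
#' @param object an \code{InitiationEventTrain}.
#' @export
setMethod("show", "InitiationEventTrain", function(object) {
  cat(sprintf("initiation events for %s: %d events in [%.4g, %.4g] s\n",
              object@nucleusId, length(object@times),
              object@window[1], object@window[2]))
})

#' @describeIn FluorescenceTrace-class compact display
#' @param object a \code{FluorescenceTrace}.
#' @export
setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("fluorescence trace %s (%s): %d frames, max %.3g %s\n",
              object@nucleusId, object@genotype, length(object@time),
              if (length(object@intensity)) max(object@intensity) else 0,
              object@unit))
})

#' @describeIn WaitingTimeSet-class compact display
#' @param object a \code{WaitingTimeSet}.
#' @export
setMethod("show", "WaitingTimeSet", function(object) {
  cat(sprintf("waiting times (%s): %d observed, %d censored\n",
              object@genotype, sum(!object@censored), sum(object@censored)))
})

#' @describeIn SurvivalEstimate-class compact display
#' @param object a \code{SurvivalEstimate}.
#' @export
setMethod("show", "SurvivalEstimate", function(object) {
  cat(sprintf("Kaplan-Meier survival on %d times, %g events\n",
              length(object@time), sum(object@nEvent)))
})

#' @describeIn MultiExpFit-class compact display
#' @param object a \code{MultiExpFit}.
#' @export
setMethod("show", "MultiExpFit", function(object) {
  cat(sprintf("%s%d-exponential fit: objective %.4g, %s\n",
              if (object@constrained) "constrained " else "",
              length(object@best@amplitudes), object@objective,
              if (isTRUE(object@accepted)) "accepted" else "rejected"))
  show(object@best)
})

#' @describeIn KineticRates-class compact display
#' @param object a \code{KineticRates}.
#' @export
setMethod("show", "KineticRates", function(object) {
  if (!object@valid) {
    cat(sprintf("invalid %d-state inversion: %s\n", object@nStates,
                object@reason))
    return(invisible(NULL))
  }
  cat(sprintf("%d-state kinetic rates\n", object@nStates))
  for (nm in names(object@rates)) {
    iv <- if (nrow(object@intervals) && nm %in% rownames(object@intervals))
      sprintf("  [%.3g, %.3g]", object@intervals[nm, "min"],
              object@intervals[nm, "max"]) else ""
    cat(sprintf("  %-9s %.6g /s%s\n", nm, object@rates[[nm]], iv))
  }
})

#' @describeIn DerivedKinetics-class compact display
#' @param object a \code{DerivedKinetics}.
#' @export
setMethod("show", "DerivedKinetics", function(object) {
  cat("derived kinetics\n")
  cat(sprintf("  T_ON = %.4g s, T_OFF = %.4g s, T_PAUSE = %.4g s\n",
              object@tOn, object@tOff, object@tPause))
  cat(sprintf("  p_ON = %.3g, p_OFF = %.3g, p_PAUSE = %.3g\n",
              object@pOn, object@pOff, object@pPause))
  cat(sprintf("  burst size = %.4g transcripts per ON period\n",
              object@burstSize))
})

#' @describeIn GapParams-class compact display
#' @param object a \code{GapParams}.
#' @export
setMethod("show", "GapParams", function(object) {
  cat(sprintf("mixed-gamma gap: p1 = %.3g, p2 = %.3g, p3 = %.3g, b = %.4g s\n",
              object@p1, object@p2, 1 - object@p1 - object@p2, object@b))
})
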