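#' Construct a single-polymerase signal kernel
#'
#' Defaults describe a reporter with a 41 bp pre-MS2 fragment, a 1292 bp
#' 24xMS2 cassette and a 4526 bp post-MS2 fragment, elongated at
#' 45 bp/s with no retention of the finished transcript at the site.
#'
#' @param preLen pre-MS2 fragment length (bp).
#' @param ms2Len MS2 cassette length (bp).
#' @param postLen post-MS2 fragment length (bp).
#' @param speed Pol II elongation speed (bp/s).
#' @param retention retention time of the finished transcript (s).
#' @return a [SignalKernel-class].
#' @examples
#' k <- signalKernel()
#' kernelBreaks(k)  # ramp start/end and signal end, in s
#' @export
signalKernel <- function(preLen = 41, ms2Len = 1292, postLen = 4526,
                         speed = 45, retention = 0) {
  new("SignalKernel", preLen = preLen, ms2Len = ms2Len, postLen = postLen,
      speed = speed, retention = retention)
}

#' Characteristic times of a signal kernel
#'
#' @param kernel a [SignalKernel-class].
#' @return named numeric: \code{rampStart} (pre-MS2 transcribed),
#'   \code{rampEnd} (cassette fully transcribed) and \code{dwellEnd}
#'   (polymerase done and transcript released), in s.
#' @export
kernelBreaks <- function(kernel) {
  stopifnot(is(kernel, "SignalKernel"))
  c(rampStart = kernel@preLen / kernel@speed,
    rampEnd = (kernel@preLen + kernel@ms2Len) / kernel@speed,
    dwellEnd = (kernel@preLen + kernel@ms2Len + kernel@postLen) /
      kernel@speed + kernel@retention)
}

#' Fluorescence of one polymerase at time tau after initiation
#'
#' Zero before the polymerase reaches the MS2 cassette, rising linearly
#' with the fraction of stem loops transcribed, one (full polymerase
#' unit) while the polymerase transcribes the post-MS2 fragment, and
#' zero after release.
#'
#' @param kernel a [SignalKernel-class].
#' @param tau numeric times since initiation (s), all >= 0.
#' @return numeric intensities in polymerase units.
#' @examples
#' k <- signalKernel()
#' kernelIntensity(k, c(0, 15, 80, 200))
#' @export
kernelIntensity <- function(kernel, tau) {
  stopifnot(is(kernel, "SignalKernel"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  b <- kernelBreaks(kernel)
  out <- numeric(length(tau))
  ramp <- tau > b["rampStart"] & tau < b["rampEnd"]
  out[ramp] <- (tau[ramp] - b["rampStart"]) / (b["rampEnd"] - b["rampStart"])
  out[tau >= b["rampEnd"] & tau <= b["dwellEnd"]] <- 1
  out
}

#' Time integral of the signal kernel
#'
#' Closed-form area under the trapezoid: the plateau duration plus half
#' the ramp, in polymerase-unit seconds.
#'
#' @param kernel a [SignalKernel-class].
#' @return numeric scalar.
#' @export
kernelIntegral <- function(kernel) {
  b <- kernelBreaks(kernel)
  unname((b["rampEnd"] - b["rampStart"]) / 2 + (b["dwellEnd"] - b["rampEnd"]))
}
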