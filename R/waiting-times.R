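#' Stable-signal window of a trace
#'
#' Restricts analysis to the stable part of the signal: the window runs
#' from the first to the last frame whose intensity reaches one fifth
#' of the trace maximum.
#'
#' @param trace a [FluorescenceTrace-class].
#' @return numeric c(t_entry, t_exit), or \code{NULL} for an all-zero
#'   trace (no analyzable signal).
#' @examples
#' tr <- fluorescenceTrace("n", 0:7 * 3.86, c(0, 0, 5, 9, 10, 4, 1, 0))
#' windowTrace(tr)
#' @export
windowTrace <- function(trace) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!length(trace@intensity)) stop("empty trace")
  m <- max(trace@intensity)
  if (m <= 0) return(NULL)
  idx <- which(trace@intensity >= m / 5)
  c(trace@time[idx[1]], trace@time[idx[length(idx)]])
}

#' Extract inter-initiation waiting times from an event train
#'
#' Waiting times are differences between successive initiation events
#' inside the window. The interval from the window start to the first
#' event is discarded (it is not a renewal interval from an observed
#' event); the final open interval from the last event to the window
#' end is appended as right-censored unless \code{censorFinal = FALSE}.
#'
#' @param train an [InitiationEventTrain-class].
#' @param window numeric c(t_entry, t_exit); defaults to the train
#'   window.
#' @param censorFinal append the final open interval as a censored
#'   observation (default TRUE).
#' @param genotype tag for the resulting set.
#' @return a [WaitingTimeSet-class].
#' @examples
#' tr <- initiationEventTrain("n", c(10, 19, 31), window = c(0, 40))
#' extractWaitingTimes(tr)  # observed 9, 12; censored 9
#' @export
extractWaitingTimes <- function(train, window = train@window,
                                censorFinal = TRUE,
                                genotype = "unknown") {
  stopifnot(is(train, "InitiationEventTrain"))
  if (length(window) != 2L || window[2] < window[1])
    stop("invalid window")
  ev <- train@times[train@times >= window[1] & train@times <= window[2]]
  dt <- if (length(ev) >= 2L) diff(ev) else numeric(0)
  cen <- rep(FALSE, length(dt))
  if (censorFinal && length(ev) >= 1L) {
    tail <- window[2] - ev[length(ev)]
    if (tail > 0) {
      dt <- c(dt, tail)
      cen <- c(cen, TRUE)
    }
  }
  new("WaitingTimeSet", deltaT = dt, censored = cen, genotype = genotype,
      nucleusId = rep(train@nucleusId, length(dt)))
}

#' Construct a waiting-time set directly
#'
#' @param deltaT numeric positive waiting times (s).
#' @param censored logical flags (default all observed).
#' @param genotype tag.
#' @param nucleusId per-observation source ids.
#' @return a [WaitingTimeSet-class].
#' @export
waitingTimeSet <- function(deltaT, censored = rep(FALSE, length(deltaT)),
                           genotype = "unknown",
                           nucleusId = rep(NA_character_, length(deltaT))) {
  new("WaitingTimeSet", deltaT = as.numeric(deltaT),
      censored = as.logical(censored), genotype = genotype,
      nucleusId = as.character(nucleusId))
}

#' Pool waiting-time sets of one genotype
#'
#' Concatenates sets from several movies of the same genotype,
#' preserving censoring flags and nucleus provenance. Order-invariant.
#'
#' @param sets list of [WaitingTimeSet-class] objects with a common
#'   genotype tag.
#' @return a pooled [WaitingTimeSet-class].
#' @export
poolGenotype <- function(sets) {
  stopifnot(is.list(sets))
  if (!length(sets))
    return(waitingTimeSet(numeric(0), logical(0)))
  tags <- unique(vapply(sets, function(s) s@genotype, character(1)))
  if (length(tags) > 1L)
    stop("cannot pool mixed genotypes: ", paste(tags, collapse = ", "))
  new("WaitingTimeSet",
      deltaT = unlist(lapply(sets, function(s) s@deltaT)),
      censored = unlist(lapply(sets, function(s) s@censored)),
      genotype = tags,
      nucleusId = unlist(lapply(sets, function(s) s@nucleusId)))
}

#' Kaplan-Meier survival estimate with Greenwood bands
#'
#' Product-limit estimator of the waiting-time survival function with
#' right censoring; the pointwise 95% confidence band uses Greenwood's
#' variance with a normal approximation on the survival scale, clipped
#' to [0, 1] (a complementary log-log transform is available).
#'
#' @param set a [WaitingTimeSet-class] with at least one observed
#'   (uncensored) waiting time.
#' @param confType "plain" (Greenwood, linear scale) or "log-log".
#' @return a [SurvivalEstimate-class] whose grid starts at t = 0 with
#'   S = 1.
#' @examples
#' s <- kmSurvival(waitingTimeSet(c(1, 2, 3)))
#' s@surv  # 1, 2/3, 1/3, 0
#' @export
kmSurvival <- function(set, confType = c("plain", "log-log")) {
  stopifnot(is(set, "WaitingTimeSet"))
  confType <- match.arg(confType)
  if (!any(!set@censored))
    stop("all waiting times are censored; survival is not estimable")
  fit <- survival::survfit(
    survival::Surv(set@deltaT, !set@censored) ~ 1,
    conf.type = if (confType == "plain") "plain" else "log-log",
    conf.int = 0.95)
  keep <- fit$n.event > 0 | fit$n.censor > 0
  lower <- pmax(ifelse(is.na(fit$lower), 0, fit$lower), 0)
  upper <- pmin(ifelse(is.na(fit$upper), 1, fit$upper), 1)
  new("SurvivalEstimate",
      time = c(0, fit$time[keep]),
      surv = c(1, fit$surv[keep]),
      lower = c(1, lower[keep]),
      upper = c(1, upper[keep]),
      nRisk = c(fit$n, fit$n.risk[keep]),
      nEvent = c(0, fit$n.event[keep]))
}

#' Integral amplitude of a trace
#'
#' Trapezoidal area under the intensity curve over the first
#' \code{tMax} seconds (default 30 min); a proxy for total mRNA output
#' of the nucleus.
#'
#' @param trace a [FluorescenceTrace-class].
#' @param tMax upper integration limit in s.
#' @return numeric area (intensity units x s).
#' @export
integralAmplitude <- function(trace, tMax = 1800) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!length(trace@time)) stop("empty trace")
  keep <- trace@time <= tMax
  t <- trace@time[keep]; y <- trace@intensity[keep]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Cumulative activation curve and t50
#'
#' Fraction of nuclei that have shown a detectable transcription focus
#' as a function of time, and the time at which half the nuclei are
#' active.
#'
#' @param onsets numeric onset times in s; \code{NA} for nuclei that
#'   never activate.
#' @param nTotal total number of nuclei in the region of interest.
#' @return list with \code{time} (sorted onset times), \code{fraction}
#'   (cumulative active fraction) and \code{t50} (first time the
#'   fraction reaches 0.5; \code{NA} if never reached).
#' @export
activationStats <- function(onsets, nTotal = length(onsets)) {
  if (nTotal <= 0) stop("'nTotal' must be positive")
  t <- sort(onsets[!is.na(onsets)])
  frac <- seq_along(t) / nTotal
  t50 <- if (any(frac >= 0.5)) t[which(frac >= 0.5)[1]] else NA_real_
  list(time = t, fraction = frac, t50 = t50)
}
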