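#' Invert a biexponential distribution to telegraph-model rates
#'
#' Closed-form solution of the inverse problem for the ON-OFF
#' telegraph model: with amplitude-weighted power sums S_k of the
#' fitted exponents,
#' k_ini = -S1, k1_minus = S1 - S2/S1 and
#' k1_plus = (S3 S1 - S2^2) / (S1 (S1^2 - S2)).
#' The result is flagged invalid when a rate is non-positive or a
#' denominator vanishes (ill-posed input).
#'
#' @param params a [MultiExpParams-class] with N = 2.
#' @return a [KineticRates-class].
#' @examples
#' p <- forwardDistribution(promoterModel(1/24, 1/242, 1/9))
#' kineticRates(invertTwoState(p))  # recovers 1/24, 1/242, 1/9
#' @export
invertTwoState <- function(params) {
  stopifnot(is(params, "MultiExpParams"))
  if (length(params@amplitudes) != 2L)
    stop("two-state inversion needs exactly 2 exponential components")
  m <- momentSums(params)
  bad <- function(reason)
    new("KineticRates", nStates = 2L,
        rates = c(k1_plus = NA_real_, k1_minus = NA_real_, k_ini = NA_real_),
        valid = FALSE, reason = reason,
        intervals = matrix(numeric(0), 0, 0))
  scale <- max(abs(params@exponents))
  if (abs(m$S1) < 1e-12 * scale) return(bad("S1 vanishes"))
  den <- m$S1 * (m$S1^2 - m$S2)
  if (abs(den) < 1e-12 * scale^3) return(bad("denominator vanishes (ill-posed)"))
  kIni <- -m$S1
  k1m <- m$S1 - m$S2 / m$S1
  k1p <- (m$S3 * m$S1 - m$S2^2) / den
  rates <- c(k1_plus = k1p, k1_minus = k1m, k_ini = kIni)
  if (any(!is.finite(rates)) || any(rates <= 0))
    return(bad("non-positive recovered rate"))
  new("KineticRates", nStates = 2L, rates = rates, valid = TRUE,
      reason = "", intervals = matrix(numeric(0), 0, 0))
}

#' Invert a three-exponential distribution to pause-model rates
#'
#' Closed-form solution of the inverse problem for the three-state
#' model with non-obligatory pausing (states OFF, ON, PAUSE; initiation
#' only in ON). Uses the amplitude-weighted power sums S1..S3 and the
#' symmetric functions L1 = sum(lambda), L2 = sum of pairwise products,
#' L3 = product of the exponents. The two inactive states enter
#' symmetrically, so output is canonicalized with k2_plus <= k1_plus:
#' PAUSE is the longer-lived inactive state.
#'
#' @param params a [MultiExpParams-class] with N = 3.
#' @return a [KineticRates-class]; invalid (with reason "ill-posed")
#'   when the discriminant (S1 L1 - S2)^2 - 4 L3 S1 is negative.
#' @export
invertThreeState <- function(params) {
  stopifnot(is(params, "MultiExpParams"))
  if (length(params@amplitudes) != 3L)
    stop("three-state inversion needs exactly 3 exponential components")
  m <- momentSums(params)
  bad <- function(reason)
    new("KineticRates", nStates = 3L,
        rates = c(k1_plus = NA_real_, k1_minus = NA_real_, k_ini = NA_real_,
                  k2_plus = NA_real_, k2_minus = NA_real_),
        valid = FALSE, reason = reason,
        intervals = matrix(numeric(0), 0, 0))
  scale <- max(abs(params@exponents))
  if (abs(m$S1) < 1e-12 * scale) return(bad("S1 vanishes"))
  disc <- (m$S1 * m$L1 - m$S2)^2 - 4 * m$L3 * m$S1
  if (disc < 0) return(bad("ill-posed (negative discriminant)"))
  sq <- sqrt(disc)
  if (sq < 1e-12 * scale^2)
    return(bad("degenerate inactive states (vanishing discriminant)"))
  kIni <- -m$S1
  k2p <- 0.5 * (-m$L1 + m$S2 / m$S1 - sq / m$S1)
  k1p <- 0.5 * (-m$L1 + m$S2 / m$S1 + sq / m$S1)
  X <- -m$S1^2 * m$L1 + m$S1 * m$S2 + m$S1 * m$L2 - m$L3 +
    m$S2^2 / m$S1 - m$S3
  k2m <- 0.5 * (m$S1 - m$S2 / m$S1 + X / sq)
  k1m <- 0.5 * (m$S1 - m$S2 / m$S1 - X / sq)
  ## canonical labeling: PAUSE is the longer-lived inactive state
  if (k2p > k1p) {
    tmp <- c(k1p, k1m)
    k1p <- k2p; k1m <- k2m
    k2p <- tmp[1]; k2m <- tmp[2]
  }
  rates <- c(k1_plus = k1p, k1_minus = k1m, k_ini = kIni,
             k2_plus = k2p, k2_minus = k2m)
  if (any(!is.finite(rates)) || any(rates <= 0))
    return(bad("non-positive recovered rate"))
  new("KineticRates", nStates = 3L, rates = rates, valid = TRUE,
      reason = "", intervals = matrix(numeric(0), 0, 0))
}

#' Invert fitted parameters with the model order inferred from N
#'
#' @param params a [MultiExpParams-class] with 2 or 3 components.
#' @return a [KineticRates-class].
#' @export
invertParams <- function(params) {
  switch(as.character(length(params@amplitudes)),
         "2" = invertTwoState(params),
         "3" = invertThreeState(params),
         stop("inversion is available for 2 or 3 exponential components"))
}

#' Promoter model from recovered kinetic rates
#'
#' @param rates a valid [KineticRates-class].
#' @return a [PromoterModel-class].
#' @export
modelFromRates <- function(rates) {
  stopifnot(is(rates, "KineticRates"))
  if (!rates@valid) stop("cannot build a model from invalid rates: ",
                         rates@reason)
  r <- rates@rates
  if (rates@nStates == 2L)
    promoterModel(r[["k1_plus"]], r[["k1_minus"]], r[["k_ini"]])
  else
    promoterModel(r[["k1_plus"]], r[["k1_minus"]], r[["k_ini"]],
                  r[["k2_plus"]], r[["k2_minus"]])
}

#' @rdname derivedKinetics
#' @export
setMethod("derivedKinetics", "KineticRates", function(model) {
  derivedKinetics(modelFromRates(model))
})

#' Full kinetics report with error intervals
#'
#' Inverts the best fit and every retained suboptimal solution within
#' the overflow ratio, and reports per-rate and per-derived-quantity
#' minima and maxima (the smallest and largest values among optimal
#' and close-to-optimal solutions).
#'
#' @param fit an accepted [MultiExpFit-class].
#' @param overflowRatio objective overflow ratio (default 2).
#' @return list with elements \code{rates} (a [KineticRates-class] for
#'   the best fit, its \code{intervals} slot filled from the valid
#'   solutions), \code{derived} (a [DerivedKinetics-class]),
#'   \code{derivedIntervals} (matrix), \code{nSolutions} and
#'   \code{flagged} (TRUE when the best-fit inversion is invalid and
#'   intervals come from valid suboptimal solutions only).
#' @export
kineticsReport <- function(fit, overflowRatio = 2) {
  stopifnot(is(fit, "MultiExpFit"))
  sols <- .retainedSolutions(fit, overflowRatio)
  inv <- lapply(sols, function(s) invertParams(s$params))
  bestRates <- inv[[1]]
  valid <- Filter(function(r) r@valid, inv)
  flagged <- !bestRates@valid
  if (!length(valid))
    stop("no solution within the overflow ratio has a valid inversion")
  rateMat <- vapply(valid, function(r) r@rates,
                    numeric(length(bestRates@rates)))
  intervals <- cbind(min = apply(rateMat, 1L, min),
                     max = apply(rateMat, 1L, max))
  rownames(intervals) <- names(bestRates@rates)
  report <- if (flagged) valid[[1]] else bestRates
  report@intervals <- intervals
  derived <- derivedKinetics(report)
  dk <- vapply(valid, function(r) {
    d <- derivedKinetics(r)
    c(T_ON = d@tOn, T_OFF = d@tOff, T_PAUSE = d@tPause,
      p_ON = d@pOn, p_OFF = d@pOff, p_PAUSE = d@pPause,
      burst_size = d@burstSize)
  }, numeric(7))
  derivedIntervals <- cbind(min = apply(dk, 1L, min),
                            max = apply(dk, 1L, max))
  list(rates = report, derived = derived,
       derivedIntervals = derivedIntervals,
       nSolutions = length(valid), flagged = flagged)
}

#' Write a kinetics report as JSON
#'
#' @param report output of [kineticsReport()].
#' @param path file path.
#' @export
writeKineticsReport <- function(report, path) {
  r <- report$rates
  d <- report$derived
  iv <- function(m) apply(m, 1L, function(x) list(min = x[[1]], max = x[[2]]),
                          simplify = FALSE)
  out <- list(
    schema = "burstKinetics/kinetics-report/1",
    model = if (r@nStates == 2L) "2state" else "3state",
    rates = as.list(r@rates),
    rate_intervals = iv(r@intervals),
    derived = list(T_ON = d@tOn, T_OFF = d@tOff, T_PAUSE = d@tPause,
                   p_ON = d@pOn, p_OFF = d@pOff, p_PAUSE = d@pPause,
                   burst_size = d@burstSize),
    derived_intervals = iv(report$derivedIntervals),
    n_solutions = report$nSolutions,
    flagged = report$flagged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
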