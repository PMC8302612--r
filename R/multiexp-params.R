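#' Construct multiexponential survival parameters
#'
#' Components are stored sorted by exponent, descending, so the slowest
#' decaying (dominant long-time) component comes first.
#'
#' @param amplitudes numeric A_1..A_N, must sum to 1.
#' @param exponents numeric lambda_1..lambda_N (1/s), all negative and
#'   pairwise distinct.
#' @return a validated [MultiExpParams-class].
#' @examples
#' multiExpParams(c(0.2, 0.8), c(-0.04, -0.12))
#' @export
multiExpParams <- function(amplitudes, exponents) {
  ord <- order(exponents, decreasing = TRUE)
  new("MultiExpParams", amplitudes = as.numeric(amplitudes[ord]),
      exponents = as.numeric(exponents[ord]))
}

#' Evaluate a multiexponential survival function
#'
#' S(t) = sum_i A_i exp(lambda_i t).
#'
#' @param params a [MultiExpParams-class].
#' @param t numeric times in s, all >= 0.
#' @return numeric S(t), same length as \code{t}.
#' @export
multiExpSurvival <- function(params, t) {
  stopifnot(is(params, "MultiExpParams"))
  if (any(t < 0)) stop("'t' must be non-negative")
  drop(exp(outer(t, params@exponents)) %*% params@amplitudes)
}

#' Density of the multiexponential waiting-time distribution
#'
#' f(t) = -dS/dt = -sum_i A_i lambda_i exp(lambda_i t).
#'
#' @inheritParams multiExpSurvival
#' @return numeric f(t).
#' @export
multiExpDensity <- function(params, t) {
  stopifnot(is(params, "MultiExpParams"))
  if (any(t < 0)) stop("'t' must be non-negative")
  -drop(exp(outer(t, params@exponents)) %*%
          (params@amplitudes * params@exponents))
}

#' @rdname momentSums
#' @export
setMethod("momentSums", "MultiExpParams", function(params) {
  A <- params@amplitudes; lam <- params@exponents
  out <- list(S1 = sum(A * lam), S2 = sum(A * lam^2), S3 = sum(A * lam^3))
  if (length(lam) == 3L) {
    out$L1 <- sum(lam)
    out$L2 <- lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]
    out$L3 <- lam[1] * lam[2] * lam[3]
  }
  out
})

#' Sample waiting times directly from a multiexponential distribution
#'
#' Draws from the hyperexponential mixture: a component i is chosen with
#' probability A_i, then an exponential with rate -lambda_i. Requires
#' all amplitudes non-negative (true for the interval distributions of
#' the promoter models supported here).
#'
#' @param params a [MultiExpParams-class] with non-negative amplitudes.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of n waiting times in s.
#' @export
sampleWaitingTimes <- function(params, n, seed = NULL) {
  stopifnot(is(params, "MultiExpParams"))
  if (any(params@amplitudes < 0))
    stop("direct sampling requires non-negative amplitudes")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(params@amplitudes), n, replace = TRUE,
                     prob = params@amplitudes)
  stats::rexp(n, rate = -params@exponents[comp])
}
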