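#' Construct mixed-gamma gap parameters
#'
#' @param p1 probability that activation needs one rate-limiting step.
#' @param p2 probability of two steps (three-step weight is
#'   1 - p1 - p2).
#' @param b mean step duration in s.
#' @return a [GapParams-class].
#' @export
gapParams <- function(p1, p2, b) {
  new("GapParams", p1 = as.numeric(p1), p2 = as.numeric(p2),
      b = as.numeric(b))
}

#' Survival function of the postmitotic gap
#'
#' Mixed-gamma model of the delay between mitosis and first
#' activation:
#' S(t) = p1 exp(-t/b) + p2 (1 - P(2, t/b)) + (1 - p1 - p2)
#' (1 - P(3, t/b)), where P(a, x) is the regularized lower incomplete
#' gamma function, i.e. a mixture of Erlang(1..3) survival functions
#' with common mean step duration b. (With the unregularized lower
#' incomplete gamma this reads gamma(2, t/b)/1 and gamma(3, t/b)/2;
#' the Gamma(a) normalizers make the two forms identical.)
#'
#' @param t numeric times in s, >= 0.
#' @param params a [GapParams-class].
#' @return numeric survival probabilities; S(0) = 1.
#' @examples
#' gapSurvival(c(0, 60), gapParams(0, 0, 60))  # Erlang-3 survival
#' @export
gapSurvival <- function(t, params) {
  stopifnot(is(params, "GapParams"))
  if (any(t < 0)) stop("'t' must be non-negative")
  p3 <- 1 - params@p1 - params@p2
  params@p1 * stats::pgamma(t, shape = 1, scale = params@b,
                            lower.tail = FALSE) +
    params@p2 * stats::pgamma(t, shape = 2, scale = params@b,
                              lower.tail = FALSE) +
    p3 * stats::pgamma(t, shape = 3, scale = params@b,
                       lower.tail = FALSE)
}

#' Sample postmitotic onset delays
#'
#' Mixture draw: the number of rate-limiting steps k in {1, 2, 3} is
#' chosen with probabilities (p1, p2, 1 - p1 - p2), then the delay is
#' Erlang(k) with mean step duration b.
#'
#' @param params a [GapParams-class].
#' @param n number of delays.
#' @param seed optional integer seed.
#' @return numeric vector of onset delays in s.
#' @export
sampleGap <- function(params, n, seed = NULL) {
  stopifnot(is(params, "GapParams"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  p3 <- 1 - params@p1 - params@p2
  k <- sample.int(3L, n, replace = TRUE, prob = c(params@p1, params@p2, p3))
  stats::rgamma(n, shape = k, scale = params@b)
}

#' Fit the mixed-gamma gap model to onset delays
#'
#' Estimates (p1, p2, b) by fitting the mixed-gamma survival to the
#' Kaplan-Meier estimate of the onset delays with the same mixed
#' linear/log objective used for waiting-time regression (three free
#' parameters: a softmax over the step-count probabilities and log b).
#'
#' @param onsets numeric onset delays in s (>= 50 required).
#' @param config a [fitConfig()] list (alpha, nStarts, seed reused).
#' @return a [GapParams-class] with the achieved objective attached as
#'   attribute \code{"objective"}.
#' @export
fitGap <- function(onsets, config = fitConfig()) {
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) < 50L)
    stop("at least 50 onset delays are required")
  surv <- kmSurvival(waitingTimeSet(onsets, genotype = "onsets"))
  ## the mixed-gamma survival is smooth and has 3 free parameters; a
  ## few hundred grid points and starts are ample
  g <- .evalGrid(surv, min(config$evalMaxPoints, 800L), config$riskFloor)
  set.seed(config$seed)
  nStarts <- min(config$nStarts, 8L)
  erlSurv <- function(b) vapply(1:3, function(k)
    stats::pgamma(g$t, k, scale = b, lower.tail = FALSE), numeric(length(g$t)))
  obj <- function(theta) {
    p <- .softmax(theta[1:2])
    b <- exp(theta[3])
    S <- drop(erlSurv(b) %*% p)
    if (any(S <= 0)) return(1e9)
    mean(config$alpha * (S - g$Se)^2 +
           (1 - config$alpha) * (log(S) - log(g$Se))^2)
  }
  gr <- function(theta) {
    p <- .softmax(theta[1:2])
    b <- exp(theta[3])
    E <- erlSurv(b)
    S <- drop(E %*% p)
    if (any(S <= 0)) return(rep(0, 3))
    n <- length(S)
    dOdS <- (2 / n) * (config$alpha * (S - g$Se) +
                         (1 - config$alpha) * (log(S) - log(g$Se)) / S)
    u <- g$t / b
    ## dS_k/db = u^(k-1) e^(-u) / Gamma(k) * t / b^2; d(b)/d(log b) = b
    dSdb <- sapply(1:3, function(k)
      u^(k - 1) * exp(-u) / gamma(k) * g$t / b^2)
    gz <- vapply(1:2, function(m)
      sum(dOdS * p[m] * (E[, m] - S)), numeric(1))
    c(gz, sum(dOdS * drop(dSdb %*% p)) * b)
  }
  best <- NULL
  for (s in seq_len(nStarts)) {
    theta0 <- c(stats::rnorm(2, 0, 1), log(stats::runif(1, 0.2, 2) *
                                             mean(onsets) / 2))
    fit <- tryCatch(
      stats::optim(theta0, obj, gr, method = "BFGS",
                   control = list(maxit = 300L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixed-gamma fit failed to converge")
  p <- .softmax(best$par[1:2])
  out <- gapParams(p[1], p[2], exp(best$par[3]))
  attr(out, "objective") <- best$value
  out
}

#' Check the equal-timescale (confluent) limit identity
#'
#' A three-exponential survival family degenerates, as its exponents
#' coalesce to a common value -1/b, to the span of
#' exp(-t/b), t exp(-t/b), t^2 exp(-t/b) (Jordan/derivative form).
#' Matching mixture weights gives
#' S(t) = exp(-u) (1 + (p2 + p3) u + p3 u^2 / 2), u = t/b — which is
#' exactly the mixed-gamma gap survival. This check evaluates both
#' routes (regularized incomplete gamma vs the confluent polynomial
#' form) on a test grid and compares them.
#'
#' @param params a [GapParams-class].
#' @param tol maximum absolute discrepancy allowed (default 1e-6).
#' @param b timescale used for the confluent limit; defaults to the
#'   gap parameter b (a mismatched value makes the check fail).
#' @param grid evaluation times in s.
#' @return logical; attribute \code{"maxError"} carries the measured
#'   discrepancy.
#' @export
equalLambdaLimitCheck <- function(params, tol = 1e-6, b = params@b,
                                  grid = seq(0, 10 * params@b,
                                             length.out = 201)) {
  stopifnot(is(params, "GapParams"))
  p3 <- 1 - params@p1 - params@p2
  u <- grid / b
  confluent <- exp(-u) * (1 + (params@p2 + p3) * u + p3 * u^2 / 2)
  err <- max(abs(confluent - gapSurvival(grid, params)))
  out <- err <= tol
  attr(out, "maxError") <- err
  out
}
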