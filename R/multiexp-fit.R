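#' Settings for multiexponential survival regression
#'
#' @param alpha weight of the linear-scale term of the objective, in
#'   [0, 1]; 0.6 balances short- and long-time errors.
#' @param nStarts number of random multi-starts for the local gradient
#'   optimization.
#' @param maxIter iteration cap per local optimization.
#' @param ksCutoff short-time cutoff in s for acceptance and the
#'   goodness-of-fit KS test (default 10 s).
#' @param overflowRatio objective overflow ratio (> 1, default 2)
#'   defining which suboptimal solutions enter error intervals.
#' @param nMax largest number of exponentials tried by
#'   [selectNumStates()] (guard against unbounded escalation).
#' @param evalMaxPoints cap on survival grid points used to evaluate
#'   the objective (large grids are thinned evenly for speed).
#' @param riskFloor evaluation-grid points where fewer subjects remain
#'   at risk are excluded from the objective: the product-limit tail
#'   supported by a handful of order statistics has O(1) noise on the
#'   log scale and would otherwise dominate the log term (default 30).
#' @param seed integer seed making the multi-start reproducible.
#' @return a list of class \code{FitConfig}.
#' @export
fitConfig <- function(alpha = 0.6, nStarts = 24, maxIter = 400,
                      ksCutoff = 10, overflowRatio = 2, nMax = 4,
                      evalMaxPoints = 3000, riskFloor = 30, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, overflowRatio > 1, nStarts >= 1)
  structure(list(alpha = alpha, nStarts = as.integer(nStarts),
                 maxIter = as.integer(maxIter), ksCutoff = ksCutoff,
                 overflowRatio = overflowRatio, nMax = as.integer(nMax),
                 evalMaxPoints = as.integer(evalMaxPoints),
                 riskFloor = as.integer(riskFloor),
                 seed = as.integer(seed)),
            class = "FitConfig")
}

## Objective on raw amplitude/exponent vectors over an evaluation grid.
.objectiveAL <- function(A, lam, t, Se, alpha) {
  S <- drop(exp(outer(t, lam)) %*% A)
  if (any(S <= 0)) return(1e9 + sum(pmin(S, 0)^2))
  mean(alpha * (S - Se)^2 + (1 - alpha) * (log(S) - log(Se))^2)
}

## Evaluation grid for the fitting objective. The product-limit
## estimate is a right-continuous step function; evaluating it exactly
## at its jump points understates the survival there by about one
## count, which compounds through the log term deep in the tail. The
## objective is therefore evaluated at the midpoints of the constancy
## intervals, where the step value is an unbiased estimate of the
## parametric survival. Zero-survival intervals are excluded (count
## reported); large grids are thinned evenly for speed.
.evalGrid <- function(surv, maxPoints, riskFloor = 1L) {
  tt <- surv@time
  ss <- surv@surv
  n <- length(tt)
  if (n < 2L) return(list(t = numeric(0), Se = numeric(0), nDropped = 0L))
  mid <- (tt[-n] + tt[-1]) / 2
  val <- ss[-n]
  keep <- which(val > 0 & surv@nRisk[-n] >= riskFloor)
  nDropped <- (n - 1L) - length(keep)
  if (length(keep) > maxPoints)
    keep <- keep[unique(round(seq(1, length(keep), length.out = maxPoints)))]
  list(t = mid[keep], Se = val[keep], nDropped = nDropped)
}

#' Mixed linear/log fitting objective
#'
#' O = (alpha/n) sum (S - S_e)^2 + ((1-alpha)/n) sum (log S - log S_e)^2,
#' evaluated at the midpoints of the constancy intervals of the
#' product-limit step function (evaluating a right-continuous step
#' estimator exactly at its jump points understates the survival by
#' about one count, which biases the log-scale term in the tail).
#' Intervals where the empirical survival is zero are excluded (their
#' count is attached as attribute \code{"nDropped"}).
#'
#' @param params a [MultiExpParams-class].
#' @param surv a [SurvivalEstimate-class].
#' @param alpha linear-scale weight in [0, 1].
#' @return numeric objective value.
#' @examples
#' s <- kmSurvival(waitingTimeSet(c(1, 2, 4, 8)))
#' fitObjective(multiExpParams(c(0.5, 0.5), c(-0.1, -0.5)), s)
#' @export
fitObjective <- function(params, surv, alpha = 0.6) {
  stopifnot(is(params, "MultiExpParams"), is(surv, "SurvivalEstimate"))
  g <- .evalGrid(surv, .Machine$integer.max)
  out <- .objectiveAL(params@amplitudes, params@exponents, g$t, g$Se, alpha)
  attr(out, "nDropped") <- g$nDropped
  out
}

## Build MultiExpParams from optimizer output, nudging exponents apart
## if the optimizer has collapsed two components (nested-model case).
.makeParams <- function(A, lam) {
  ord <- order(lam, decreasing = TRUE)
  A <- A[ord]; lam <- lam[ord]
  scale <- max(abs(lam))
  for (i in seq_along(lam)[-1]) {
    if (abs(lam[i] - lam[i - 1]) < 1e-9 * scale)
      lam[i] <- lam[i - 1] - 1e-8 * scale
  }
  multiExpParams(A, lam)
}

.softmax <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

#' Fit an N-exponential survival function
#'
#' Minimizes the mixed linear/log objective over the 2N-1 free
#' parameters (N-1 amplitude logits with the unit-sum constraint
#' enforced by a softmax, and log-transformed decay rates), using
#' multiple initial guesses followed by local gradient (BFGS)
#' optimization with an analytic gradient. Initial guesses come from a
#' coarse screen of candidate decay-rate sets spanning the observed
#' time range (half log-uniform, half anchored at reciprocal
#' survival-crossing times), with amplitudes from least squares at
#' fixed exponents; the best mutually distinct candidates are polished.
#' All local optima are retained; the best is the fit, the rest feed
#' [errorIntervals()].
#'
#' @param surv a [SurvivalEstimate-class].
#' @param N number of exponentials (>= 2; use N = 1 only for the
#'   degenerate Poisson check).
#' @param config a [fitConfig()] list.
#' @return a [MultiExpFit-class]; the acceptance flag is filled by
#'   comparison with the Greenwood band above the short-time cutoff.
#' @export
fitMultiExp <- function(surv, N, config = fitConfig()) {
  stopifnot(is(surv, "SurvivalEstimate"), N >= 1)
  g <- .evalGrid(surv, config$evalMaxPoints, config$riskFloor)
  if (length(g$t) < 2 * N - 1)
    stop("survival estimate has fewer than 2N-1 informative points")
  set.seed(config$seed)
  tPos <- g$t[g$t > 0]
  rMin <- 1 / max(tPos)
  rMax <- 1 / min(tPos)

  obj <- function(theta) {
    lam <- -exp(theta[seq_len(N)])
    A <- if (N > 1L) .softmax(theta[N + seq_len(N - 1L)]) else 1
    .objectiveAL(A, lam, g$t, g$Se, config$alpha)
  }
  ## analytic gradient of the objective in the transformed parameters
  gr <- function(theta) {
    lam <- -exp(theta[seq_len(N)])
    A <- if (N > 1L) .softmax(theta[N + seq_len(N - 1L)]) else 1
    E <- exp(outer(g$t, lam))
    S <- drop(E %*% A)
    if (any(S <= 0)) return(rep(0, length(theta)))
    n <- length(S)
    dOdS <- (2 / n) * (config$alpha * (S - g$Se) +
                         (1 - config$alpha) * (log(S) - log(g$Se)) / S)
    gTheta <- vapply(seq_len(N), function(j)
      sum(dOdS * A[j] * lam[j] * g$t * E[, j]), numeric(1))
    if (N > 1L) {
      gZ <- vapply(seq_len(N - 1L), function(m)
        sum(dOdS * A[m] * (E[, m] - S)), numeric(1))
      c(gTheta, gZ)
    } else gTheta
  }

  ## Coarse screen over many candidate exponent sets (amplitudes from
  ## least squares at fixed exponents), then BFGS polishing of the
  ## best, mutually distinct candidates. The screen is cheap and makes
  ## the multi-start robust to the strong local-optimum structure of
  ## the mixed objective when timescales are well separated.
  thinIdx <- unique(round(seq(1, length(g$t),
                              length.out = min(400, length(g$t)))))
  tS <- g$t[thinIdx]; SeS <- g$Se[thinIdx]
  candTheta <- function(rates) {
    B <- exp(outer(tS, -rates))
    A0 <- tryCatch(stats::coef(stats::lm.fit(B, SeS)),
                   error = function(e) rep(1 / N, N))
    A0[!is.finite(A0)] <- 1 / N
    A0 <- pmax(A0, 1e-3); A0 <- A0 / sum(A0)
    c(log(rates), if (N > 1L) log(A0[-N] / A0[N]) else numeric(0))
  }
  ## proposals: half log-uniform over the representable range, half
  ## anchored at reciprocal survival-crossing times (concentrating
  ## candidates where the data actually decay) with log-normal jitter
  nScreen <- 300L * N
  timeAt <- function(q) {
    i <- which(g$Se <= q)[1]
    if (is.na(i)) max(g$t) else max(g$t[i], min(tPos))
  }
  logR <- t(vapply(seq_len(nScreen), function(i) {
    lr <- if (i %% 2L == 0L) {
      stats::runif(N, log(rMin), log(rMax))
    } else {
      u <- sort(stats::runif(N, 0.02, 0.98), decreasing = TRUE)
      log(1 / vapply(u, timeAt, numeric(1))) + stats::rnorm(N, 0, 0.5)
    }
    sort(pmin(pmax(lr, log(rMin)), log(rMax)))
  }, numeric(N)))
  screened <- t(apply(logR, 1L, function(lr) {
    th <- candTheta(exp(lr))
    lam <- -exp(th[seq_len(N)])
    A <- if (N > 1L) .softmax(th[N + seq_len(N - 1L)]) else 1
    c(.objectiveAL(A, lam, tS, SeS, config$alpha), th)
  }))
  ord <- order(screened[, 1L])
  ## greedy pick of starts from distinct basins (log-rate separation)
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) >= config$nStarts) break
    lr <- screened[i, 1L + seq_len(N)]
    distinct <- !length(picked) ||
      all(vapply(picked, function(j)
        max(abs(lr - screened[j, 1L + seq_len(N)])) > 0.5, logical(1)))
    if (distinct) picked <- c(picked, i)
  }
  solutions <- vector("list", length(picked))
  for (s in seq_along(picked)) {
    theta0 <- screened[picked[s], -1L]
    fit <- tryCatch(
      stats::optim(theta0, obj, gr, method = "BFGS",
                   control = list(maxit = config$maxIter,
                                  reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    lam <- -exp(fit$par[seq_len(N)])
    if (any(!is.finite(lam)) || any(lam >= 0)) next
    A <- if (N > 1L) .softmax(fit$par[N + seq_len(N - 1L)]) else 1
    if (any(!is.finite(A))) next
    solutions[[s]] <- list(params = .makeParams(A, lam),
                           objective = fit$value)
  }
  solutions <- Filter(Negate(is.null), solutions)
  if (!length(solutions))
    stop("multiexponential regression failed to converge on any of ",
         config$nStarts, " starts; inspect the survival estimate")
  ord <- order(vapply(solutions, `[[`, numeric(1), "objective"))
  solutions <- solutions[ord]
  best <- solutions[[1]]
  fitObj <- new("MultiExpFit", best = best$params,
                objective = best$objective,
                suboptimal = solutions[-1],
                accepted = NA, ksP = NA_real_, alpha = config$alpha,
                constrained = FALSE)
  fitObj@accepted <- acceptFit(fitObj, surv, config$ksCutoff,
                               config$riskFloor)
  fitObj
}

#' Acceptance check against the Greenwood band
#'
#' A regression is acceptable when the parametric survival stays inside
#' the pointwise 95% confidence bounds of the empirical survival at
#' every grid time at or above the short-time cutoff (short times are
#' excluded for the same reason as in the cutoff KS test: residual
#' deconvolution errors concentrate there). Grid times where fewer
#' than \code{riskFloor} subjects remain at risk are also excluded:
#' the normal-approximation band collapses there around a survival
#' estimate supported by a handful of order statistics.
#'
#' @param fit a [MultiExpFit-class] or [MultiExpParams-class].
#' @param surv a [SurvivalEstimate-class].
#' @param ksCutoff cutoff time in s (default 10).
#' @param riskFloor minimum number at risk for a grid time to count
#'   (default 30).
#' @return logical.
#' @export
acceptFit <- function(fit, surv, ksCutoff = 10, riskFloor = 30) {
  params <- if (is(fit, "MultiExpFit")) fit@best else fit
  stopifnot(is(params, "MultiExpParams"), is(surv, "SurvivalEstimate"))
  keep <- surv@time >= ksCutoff & surv@nRisk >= riskFloor
  if (!any(keep)) stop("no survival grid times at or above the cutoff")
  S <- multiExpSurvival(params, surv@time[keep])
  all(S >= surv@lower[keep] - 1e-12 & S <= surv@upper[keep] + 1e-12)
}

#' Select the number of promoter states by parsimony
#'
#' Progressively increases the number of exponentials starting at
#' N = 2 until an acceptable regression (inside the Greenwood band
#' above the cutoff) is reached. N equals the number of promoter
#' states of the corresponding Markov model.
#'
#' @param surv a [SurvivalEstimate-class].
#' @param config a [fitConfig()] list; \code{nMax} caps the escalation.
#' @return the first accepted [MultiExpFit-class]; the number of
#'   exponentials is \code{length(amplitudes(fit@best))}. Rejected
#'   fits are attached as attribute \code{"rejected"}.
#' @export
selectNumStates <- function(surv, config = fitConfig()) {
  rejected <- list()
  for (N in 2:config$nMax) {
    fit <- fitMultiExp(surv, N, config)
    if (isTRUE(fit@accepted)) {
      attr(fit, "rejected") <- rejected
      return(fit)
    }
    rejected[[as.character(N)]] <- fit
  }
  stop("no acceptable fit up to N = ", config$nMax,
       "; more data (or a longer observation window) is needed")
}

#' Constrained fit of the obligatory-pause model
#'
#' Under obligatory pausing every initiation passes through the paused
#' state, which forces the waiting-time density to vanish at t = 0;
#' equivalently the distribution parameters satisfy the linear
#' constraint sum_i A_i lambda_i = 0, leaving four free parameters
#' instead of five. The fit is restricted to that manifold (amplitudes
#' may be negative there; the search penalizes non-positive survival
#' values) and acceptance is evaluated as in [acceptFit()].
#'
#' @inheritParams fitMultiExp
#' @return a [MultiExpFit-class] with \code{constrained = TRUE}.
#' @export
fitConstrainedObligatory <- function(surv, config = fitConfig()) {
  stopifnot(is(surv, "SurvivalEstimate"))
  g <- .evalGrid(surv, config$evalMaxPoints, config$riskFloor)
  if (length(g$t) < 4L)
    stop("survival estimate has fewer than 4 informative points")
  set.seed(config$seed + 1L)
  tPos <- g$t[g$t > 0]
  rMin <- 1 / max(tPos)
  rMax <- 1 / min(tPos)

  expand <- function(theta) {
    lam <- sort(-exp(theta[1:3]), decreasing = TRUE)
    A1 <- theta[4]
    ## A1 l1 + A2 l2 + (1 - A1 - A2) l3 = 0
    A2 <- -(lam[3] + A1 * (lam[1] - lam[3])) / (lam[2] - lam[3])
    list(A = c(A1, A2, 1 - A1 - A2), lam = lam)
  }
  obj <- function(theta) {
    p <- expand(theta)
    .objectiveAL(p$A, p$lam, g$t, g$Se, config$alpha)
  }

  solutions <- list()
  for (s in seq_len(config$nStarts)) {
    rates <- sort(exp(stats::runif(3, log(rMin), log(rMax))))
    theta0 <- c(log(rates), stats::runif(1, 0.05, 0.6))
    fit <- tryCatch(
      stats::optim(theta0, obj, method = "BFGS",
                   control = list(maxit = config$maxIter, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    p <- expand(fit$par)
    if (any(!is.finite(p$lam)) || any(p$lam >= 0) || any(!is.finite(p$A)))
      next
    solutions[[length(solutions) + 1L]] <-
      list(params = .makeParams(p$A, p$lam), objective = fit$value)
  }
  if (!length(solutions))
    stop("constrained obligatory-pause regression failed to converge")
  ord <- order(vapply(solutions, `[[`, numeric(1), "objective"))
  solutions <- solutions[ord]
  best <- solutions[[1]]
  fitObj <- new("MultiExpFit", best = best$params,
                objective = best$objective, suboptimal = solutions[-1],
                accepted = NA, ksP = NA_real_, alpha = config$alpha,
                constrained = TRUE)
  fitObj@accepted <- acceptFit(fitObj, surv, config$ksCutoff,
                               config$riskFloor)
  fitObj
}

#' Cutoff Kolmogorov-Smirnov goodness-of-fit test
#'
#' One-sided one-sample KS test of the observed waiting times against
#' the fitted parametric distribution, restricted to times larger than
#' the cutoff (default 10 s) where the fitted distribution is
#' truncated and renormalized. Short times are excluded because small
#' systematic deconvolution errors there would otherwise dominate the
#' statistic for every model.
#'
#' @param set a [WaitingTimeSet-class]; only uncensored waiting times
#'   above the cutoff are used (at least 30 required).
#' @param fit a [MultiExpFit-class] or [MultiExpParams-class].
#' @param cutoff truncation time in s.
#' @return the KS p-value (large when the data follow the fitted
#'   distribution).
#' @export
modifiedKsTest <- function(set, fit, cutoff = 10) {
  stopifnot(is(set, "WaitingTimeSet"))
  params <- if (is(fit, "MultiExpFit")) fit@best else fit
  x <- set@deltaT[!set@censored]
  x <- x[x > cutoff]
  if (length(x) < 30L)
    stop("fewer than 30 observed waiting times above the cutoff")
  Sc <- multiExpSurvival(params, cutoff)
  pTrunc <- function(q) 1 - multiExpSurvival(params, pmax(q, cutoff)) / Sc
  stats::ks.test(x, pTrunc, alternative = "greater")$p.value
}

#' Error intervals from suboptimal solutions
#'
#' Per-parameter minimum and maximum over the best fit and every
#' retained local optimum whose objective does not exceed the best
#' objective times the overflow ratio.
#'
#' @param fit a [MultiExpFit-class].
#' @param overflowRatio number > 1 (default 2).
#' @return numeric matrix with rows A_1..A_N, lambda_1..lambda_N and
#'   columns \code{min}, \code{max}.
#' @export
errorIntervals <- function(fit, overflowRatio = 2) {
  stopifnot(is(fit, "MultiExpFit"), overflowRatio > 1)
  sols <- .retainedSolutions(fit, overflowRatio)
  P <- vapply(sols, function(s)
    c(s$params@amplitudes, s$params@exponents),
    numeric(2L * length(fit@best@amplitudes)))
  N <- length(fit@best@amplitudes)
  out <- cbind(min = apply(P, 1L, min), max = apply(P, 1L, max))
  rownames(out) <- c(sprintf("A%d", seq_len(N)),
                     sprintf("lambda%d", seq_len(N)))
  out
}

.retainedSolutions <- function(fit, overflowRatio) {
  sols <- c(list(list(params = fit@best, objective = fit@objective)),
            fit@suboptimal)
  keep <- vapply(sols, `[[`, numeric(1), "objective") <=
    overflowRatio * fit@objective + 1e-15
  sols[keep]
}
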