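#' Build the discrete grid of candidate initiation positions
#'
#' Positions are spaced \code{stepBp} base pairs apart, i.e.
#' \code{stepBp / speed} seconds — finer than the frame interval and
#' smaller than the minimum spacing between elongating polymerases, so
#' at most one initiation event can occupy a grid position.
#'
#' @param window numeric length-2 time window (s).
#' @param stepBp grid step in bp (default 30).
#' @param speed elongation speed in bp/s (default 45).
#' @return a [PositionGrid-class] with
#'   \code{nPositions = ceiling(window length / stepS)}.
#' @examples
#' makeGrid(c(0, 35 * 60))  # 3150 positions
#' @export
makeGrid <- function(window, stepBp = 30, speed = 45) {
  if (stepBp <= 0 || speed <= 0) stop("grid step and speed must be positive")
  window <- as.numeric(window)
  if (length(window) != 2L || diff(window) <= 0)
    stop("'window' must have positive length")
  stepS <- stepBp / speed
  n <- as.integer(ceiling(diff(window) / stepS - 1e-9))
  new("PositionGrid", stepBp = stepBp, stepS = stepS, window = window,
      nPositions = n)
}

#' Times of the grid positions
#'
#' @param grid a [PositionGrid-class].
#' @return numeric vector of candidate initiation times (s).
#' @export
gridTimes <- function(grid) {
  stopifnot(is(grid, "PositionGrid"))
  grid@window[1] + (seq_len(grid@nPositions) - 1L) * grid@stepS
}

#' Genetic-algorithm settings for trace deconvolution
#'
#' @param populationSize individuals per generation.
#' @param nGenerations maximum generations.
#' @param pAdd,pRemove,pShift per-offspring mutation probabilities
#'   (add event at a random free position, delete a random event, shift
#'   a random event by 1-3 grid steps).
#' @param crossoverRate probability of one-point crossover on the time
#'   axis when producing an offspring.
#' @param localSweeps maximum greedy single-event-shift sweeps applied
#'   to the final solution.
#' @param fitnessTol stop when the best sum of squared residuals falls
#'   to or below this value.
#' @param nRestarts number of independently seeded GA passes; later
#'   passes run only if the previous best residual is still above
#'   \code{fitnessTol} (default 2).
#' @param minSupport minimum kernel signal energy (sum of squared
#'   kernel values over the observed frames) for a grid position to be
#'   a candidate: events initiated so close to the movie end that
#'   almost none of their signal is observed are unidentifiable and
#'   would otherwise be added freely as zero-cost ghost events.
#' @param stagnationLimit stop after this many generations without
#'   improvement.
#' @param seed integer seed (reproducibility contract).
#' @return a list of class \code{GAConfig}.
#' @export
gaConfig <- function(populationSize = 100, nGenerations = 300,
                     pAdd = 0.3, pRemove = 0.3, pShift = 0.6,
                     crossoverRate = 0.7, localSweeps = 50,
                     fitnessTol = 1e-9, stagnationLimit = 40,
                     nRestarts = 2, minSupport = 1, seed = 1L) {
  stopifnot(populationSize >= 2, nGenerations >= 1,
            crossoverRate >= 0, crossoverRate <= 1, localSweeps >= 0)
  structure(list(populationSize = as.integer(populationSize),
                 nGenerations = as.integer(nGenerations),
                 pAdd = pAdd, pRemove = pRemove, pShift = pShift,
                 crossoverRate = crossoverRate,
                 localSweeps = as.integer(localSweeps),
                 fitnessTol = fitnessTol,
                 stagnationLimit = as.integer(stagnationLimit),
                 nRestarts = as.integer(nRestarts),
                 minSupport = minSupport,
                 seed = as.integer(seed)),
            class = "GAConfig")
}

## Kernel response of every grid position at every frame time.
kernelResponseMatrix <- function(kernel, frameTimes, positionTimes) {
  tau <- outer(frameTimes, positionTimes, "-")
  neg <- tau < 0
  tau[neg] <- 0
  K <- matrix(kernelIntensity(kernel, as.vector(tau)),
              nrow = length(frameTimes))
  K[neg] <- 0
  K
}

## Sum of squared residuals for an index set, given frame signal cache.
.signalOf <- function(K, idx) {
  if (!length(idx)) return(numeric(nrow(K)))
  rowSums(K[, idx, drop = FALSE])
}

## Non-negative least-squares relaxation of the placement problem by
## cyclic coordinate descent on fractional occupancies x >= 0.
.nnlsRelaxation <- function(K, y, csq, nSweep = 60L) {
  P <- ncol(K)
  x <- numeric(P)
  r <- y
  for (s in seq_len(nSweep)) {
    changed <- FALSE
    for (j in seq_len(P)) {
      if (!is.finite(csq[j]) || csq[j] <= 0) next
      xn <- max(0, x[j] + sum(K[, j] * r) / csq[j])
      if (abs(xn - x[j]) > 1e-12) {
        r <- r - (xn - x[j]) * K[, j]
        x[j] <- xn
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  x
}

## Integer placement from a fractional occupancy profile: the k-th
## event goes where the cumulative mass crosses k - offset.
.staircaseInit <- function(x, nEvents, offset = 0.5) {
  if (nEvents < 1L) return(integer(0))
  cs <- cumsum(x)
  idx <- vapply(seq_len(nEvents) - offset, function(cr) {
    i <- which(cs >= cr)[1]
    if (is.na(i)) NA_integer_ else i
  }, integer(1))
  sort(unique(idx[!is.na(idx)]))
}

## Greedy matching-pursuit initial guess: add the single event that
## most reduces the SSR until no addition helps.
.greedyInit <- function(K, y, csq) {
  idx <- integer(0)
  r <- y
  repeat {
    g <- drop(crossprod(K, r))
    delta <- -2 * g + csq
    if (length(idx)) delta[idx] <- Inf
    j <- which.min(delta)
    if (delta[j] >= -1e-12) break
    idx <- c(idx, j)
    r <- r - K[, j]
  }
  sort(idx)
}

## Greedy single-event local optimization to convergence: each sweep
## repositions every event at its individually best grid position
## (a generalized shift), deletes events whose removal lowers the
## residual, and adds the best new event if that lowers it further.
.localOptimize <- function(K, y, idx, maxSweeps, csq = colSums(K^2)) {
  if (maxSweeps < 1L) return(sort(idx))
  r <- y - .signalOf(K, idx)
  ssr <- sum(r^2)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    ## reposition each event at its best position
    for (i in seq_along(idx)) {
      j <- idx[i]
      rBare <- r + K[, j]
      delta <- -2 * drop(crossprod(K, rBare)) + csq
      delta[setdiff(idx, j)] <- Inf
      jBest <- which.min(delta)
      ssrBare <- sum(rBare^2)
      if (ssrBare + delta[jBest] < ssr - 1e-12) {
        idx[i] <- jBest
        r <- rBare - K[, jBest]
        ssr <- ssrBare + delta[jBest]
        improved <- TRUE
      }
    }
    ## delete events that hurt
    i <- 1L
    while (i <= length(idx)) {
      j <- idx[i]
      dRem <- 2 * sum(r * K[, j]) + csq[j]
      if (dRem < -1e-12) {
        r <- r + K[, j]
        ssr <- ssr + dRem
        idx <- idx[-i]
        improved <- TRUE
      } else i <- i + 1L
    }
    ## add the best missing event while it helps
    repeat {
      delta <- -2 * drop(crossprod(K, r)) + csq
      if (length(idx)) delta[idx] <- Inf
      jBest <- which.min(delta)
      if (delta[jBest] >= -1e-12) break
      idx <- c(idx, jBest)
      r <- r - K[, jBest]
      ssr <- ssr + delta[jBest]
      improved <- TRUE
    }
    ## joint shifts of consecutive event pairs (escapes two-coordinate
    ## local minima that single-event moves cannot)
    idx <- sort(idx)
    if (length(idx) >= 2L) {
      nPos <- ncol(K)
      for (i in seq_len(length(idx) - 1L)) {
        j1 <- idx[i]; j2 <- idx[i + 1L]
        for (dlt in c(-2L, -1L, 1L, 2L)) {
          n1 <- j1 + dlt; n2 <- j2 + dlt
          if (n1 < 1L || n2 > nPos || !is.finite(csq[n1]) ||
              !is.finite(csq[n2])) next
          if ((n1 %in% idx && n1 != j1 && n1 != j2) ||
              (n2 %in% idx && n2 != j1 && n2 != j2)) next
          rNew <- r + K[, j1] + K[, j2] - K[, n1] - K[, n2]
          ssrNew <- sum(rNew^2)
          if (ssrNew < ssr - 1e-12) {
            idx[i] <- n1; idx[i + 1L] <- n2
            r <- rNew; ssr <- ssrNew
            j1 <- n1; j2 <- n2
            improved <- TRUE
          }
        }
      }
      idx <- sort(idx)
    }
    if (!improved) break
  }
  sort(idx)
}

#' Deconvolve a fluorescence trace into initiation events
#'
#' Recovers Pol II initiation times on a discrete 30 bp grid by
#' minimizing the sum of squared residuals between the trace and the
#' signal reconstructed from candidate event placements, using a
#' genetic algorithm (add/remove/shift mutations, one-point crossover
#' on the time axis, elitism) followed by greedy local optimization of
#' single-event shifts. The initial population is seeded from an
#' integral heuristic (expected event count = trace integral / kernel
#' integral) and a greedy matching-pursuit solution, which shrinks the
#' search space considerably.
#'
#' @param trace a [FluorescenceTrace-class] in polymerase units.
#' @param kernel a [SignalKernel-class].
#' @param grid a [PositionGrid-class]; defaults to a 30 bp grid over the
#'   trace extent.
#' @param config a [gaConfig()] list; the seed makes the search
#'   reproducible.
#' @return an [InitiationEventTrain-class] with event times on the
#'   grid; the achieved sum of squared residuals is attached as
#'   attribute \code{"residual"}.
#' @export
deconvolveTrace <- function(trace, kernel = signalKernel(), grid = NULL,
                            config = gaConfig()) {
  stopifnot(is(trace, "FluorescenceTrace"), is(kernel, "SignalKernel"))
  if (trace@unit != "polymerase")
    stop("trace must be calibrated to polymerase units before deconvolution")
  if (is.null(grid))
    grid <- makeGrid(c(trace@time[1],
                       trace@time[length(trace@time)] + 1e-9))
  stopifnot(is(grid, "PositionGrid"))
  if (trace@time[1] < grid@window[1] - 1e-9 ||
      trace@time[length(trace@time)] > grid@window[2] + grid@stepS + 1e-9)
    stop("trace window must lie within the grid window")
  y <- trace@intensity
  emptyTrain <- initiationEventTrain(trace@nucleusId, numeric(0),
                                     window = grid@window)
  if (all(y == 0)) {
    attr(emptyTrain, "residual") <- 0
    return(emptyTrain)
  }
  posTimes <- gridTimes(grid)
  K <- kernelResponseMatrix(kernel, trace@time, posTimes)
  csq <- colSums(K^2)
  live <- which(csq >= config$minSupport)
  if (!length(live)) {
    attr(emptyTrain, "residual") <- sum(y^2)
    return(emptyTrain)
  }
  ## positions with too little observed signal energy are not
  ## candidates (Inf support cost blocks adds and repositions there)
  csq[csq < config$minSupport] <- Inf
  nPos <- grid@nPositions

  fitness <- function(idx) sum((y - .signalOf(K, idx))^2)

  bestOverall <- integer(0)
  bestOverallFit <- Inf
  for (restart in seq_len(config$nRestarts)) {
  set.seed(config$seed + (restart - 1L) * 7919L)

  ## --- initial population ------------------------------------------
  ## Strong seeds: a non-negative least-squares relaxation rounded to
  ## integer placements at several candidate event counts, plus a
  ## greedy matching-pursuit solution; the remainder comes from the
  ## integral heuristic (expected count = trace integral / kernel
  ## integral, positions drawn along the positive finite differences).
  pop <- vector("list", config$populationSize)
  xRelax <- .nnlsRelaxation(K, y, csq)
  nRelax <- max(0L, round(sum(xRelax)))
  seeds <- list(.localOptimize(K, y, .greedyInit(K, y, csq), 5L, csq))
  for (dn in -2:2) {
    n <- nRelax + dn
    if (n < 0L) next
    for (off in c(0.5, 0.25, 0.75)) {
      seeds[[length(seeds) + 1L]] <-
        .localOptimize(K, y, .staircaseInit(xRelax, n, off), 5L, csq)
    }
  }
  seeds <- unique(seeds)
  nSeed <- min(length(seeds), config$populationSize)
  pop[seq_len(nSeed)] <- seeds[seq_len(nSeed)]
  dtFrame <- if (length(trace@time) > 1L)
    trace@time[2] - trace@time[1] else grid@stepS
  nExpect <- max(0L, round(sum(y) * dtFrame / kernelIntegral(kernel)))
  wRaw <- diff(c(0, y))
  w <- stats::approx(trace@time, pmax(wRaw, 0), xout = posTimes,
                     rule = 2)$y + 1e-6
  for (i in seq_along(pop)[seq_along(pop) > nSeed]) {
    n <- min(max(0L, nExpect + sample(-3:3, 1L)), length(live))
    pop[[i]] <- if (n > 0)
      sort(sample(live, n, prob = w[live])) else integer(0)
  }
  fit <- vapply(pop, fitness, numeric(1))

  ## --- generations --------------------------------------------------
  bestFit <- min(fit)
  stagnation <- 0L
  nElite <- max(2L, config$populationSize %/% 10L)
  for (gen in seq_len(config$nGenerations)) {
    if (bestFit <= config$fitnessTol) break
    ord <- order(fit)
    elite <- pop[ord[seq_len(nElite)]]
    eliteFit <- fit[ord[seq_len(nElite)]]
    nOff <- config$populationSize - nElite
    offspring <- vector("list", nOff)
    for (i in seq_len(nOff)) {
      p1 <- .tournament(fit)
      child <- pop[[p1]]
      if (stats::runif(1) < config$crossoverRate) {
        p2 <- .tournament(fit)
        cut <- sample.int(nPos, 1L)
        child <- sort(unique(c(pop[[p1]][pop[[p1]] < cut],
                               pop[[p2]][pop[[p2]] >= cut])))
      }
      if (stats::runif(1) < config$pAdd && length(child) < length(live)) {
        free <- setdiff(live, child)
        child <- sort(c(child, free[sample.int(length(free), 1L)]))
      }
      if (stats::runif(1) < config$pRemove && length(child)) {
        child <- child[-sample.int(length(child), 1L)]
      }
      if (stats::runif(1) < config$pShift && length(child)) {
        k <- sample.int(length(child), 1L)
        shift <- sample(c(-3:-1, 1:3), 1L)
        cand <- child[k] + shift
        if (cand %in% live && !(cand %in% child))
          child[k] <- cand
        child <- sort(child)
      }
      offspring[[i]] <- child
    }
    offFit <- vapply(offspring, fitness, numeric(1))
    ## memetic step: polish the best offspring with a short local
    ## optimization so the GA explores and the descent exploits
    ib <- which.min(offFit)
    offspring[[ib]] <- .localOptimize(K, y, offspring[[ib]], 2L, csq)
    offFit[ib] <- fitness(offspring[[ib]])
    pop <- c(elite, offspring)
    fit <- c(eliteFit, offFit)
    newBest <- min(fit)
    if (newBest < bestFit - 1e-12) {
      bestFit <- newBest
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
      if (stagnation >= config$stagnationLimit) break
    }
  }
  best <- pop[[which.min(fit)]]
  best <- .localOptimize(K, y, best, config$localSweeps, csq)
  best <- best[is.finite(csq[best])]   # drop unobservable positions
  bf <- fitness(best)
  if (bf < bestOverallFit) {
    bestOverall <- best
    bestOverallFit <- bf
  }
  if (bestOverallFit <= config$fitnessTol) break
  }  # restarts
  out <- initiationEventTrain(trace@nucleusId, posTimes[bestOverall],
                              window = grid@window)
  attr(out, "residual") <- bestOverallFit
  out
}

.tournament <- function(fit, size = 2L) {
  cand <- sample.int(length(fit), size)
  cand[which.min(fit[cand])]
}

#' Bin initiation events per nucleus
#'
#' Counts events in consecutive time bins (default 30 s, equivalently
#' 1350 bp at 45 bp/s), producing the matrix rendered as the
#' event-density heatmap.
#'
#' @param trains list of [InitiationEventTrain-class] objects sharing a
#'   time origin.
#' @param binWidth bin width in s.
#' @param tMax end of the binned range; defaults to the latest window
#'   end among the trains.
#' @return integer matrix, one row per nucleus (ordered by id), one
#'   column per bin.
#' @export
binEvents <- function(trains, binWidth = 30, tMax = NULL) {
  stopifnot(length(trains) > 0, binWidth > 0)
  if (is.null(tMax))
    tMax <- max(vapply(trains, function(tr) tr@window[2], numeric(1)))
  nBin <- as.integer(ceiling(tMax / binWidth - 1e-9))
  breaks <- (0:nBin) * binWidth
  ids <- vapply(trains, function(tr) tr@nucleusId, character(1))
  ord <- order(ids)
  counts <- t(vapply(trains[ord], function(tr) {
    if (!length(tr@times)) return(integer(nBin))
    idx <- findInterval(tr@times, breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    tabulate(idx, nbins = nBin)
  }, integer(nBin)))
  rownames(counts) <- ids[ord]
  colnames(counts) <- sprintf("bin_%d", seq_len(nBin))
  counts
}
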