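#' Construct a promoter model
#'
#' Builds and validates a two-state (telegraph) or three-state
#' (non-obligatory pause) promoter model. The number of states is
#' implied by the rates supplied: give \code{k2Plus}/\code{k2Minus} for
#' the three-state model, omit them for the telegraph model.
#'
#' @param k1Plus OFF to ON switching rate (1/s).
#' @param k1Minus ON to OFF switching rate (1/s).
#' @param kIni Pol II initiation rate while ON (1/s).
#' @param k2Plus PAUSE to ON switching rate (1/s), 3-state only.
#' @param k2Minus ON to PAUSE switching rate (1/s), 3-state only.
#' @return a validated [PromoterModel-class].
#' @examples
#' sna <- promoterModel(k1Plus = 1/24, k1Minus = 1/242, kIni = 1/9)
#' three <- promoterModel(0.01, 0.01, 0.01, k2Plus = 0.01, k2Minus = 0.01)
#' @export
promoterModel <- function(k1Plus, k1Minus, kIni, k2Plus = NA_real_,
                          k2Minus = NA_real_) {
  threeState <- !is.na(k2Plus) || !is.na(k2Minus)
  if (threeState && (is.na(k2Plus) || is.na(k2Minus)))
    stop("a 3-state model needs both 'k2Plus' and 'k2Minus'")
  for (nm in c("k1Plus", "k1Minus", "kIni")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("rate '%s' must be a single positive finite number", nm))
  }
  if (threeState) for (nm in c("k2Plus", "k2Minus")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("rate '%s' must be a single positive finite number", nm))
  }
  new("PromoterModel", nStates = if (threeState) 3L else 2L,
      k1Plus = as.numeric(k1Plus), k1Minus = as.numeric(k1Minus),
      kIni = as.numeric(kIni),
      k2Plus = as.numeric(k2Plus), k2Minus = as.numeric(k2Minus))
}

#' Generator matrix of the promoter-state chain
#'
#' Infinitesimal generator over the fixed state ordering (OFF, ON) or
#' (OFF, ON, PAUSE); entry (i, j) is the rate from state i to state j,
#' rows sum to zero.
#'
#' @param model a [PromoterModel-class].
#' @return square numeric matrix with state dimnames.
#' @export
generatorMatrix <- function(model) {
  stopifnot(is(model, "PromoterModel"))
  if (model@nStates == 2L) {
    Q <- matrix(c(-model@k1Plus, model@k1Plus,
                  model@k1Minus, -model@k1Minus),
                2, 2, byrow = TRUE)
    dimnames(Q) <- list(c("OFF", "ON"), c("OFF", "ON"))
  } else {
    Q <- matrix(c(-model@k1Plus, model@k1Plus, 0,
                  model@k1Minus, -(model@k1Minus + model@k2Minus), model@k2Minus,
                  0, model@k2Plus, -model@k2Plus),
                3, 3, byrow = TRUE)
    dimnames(Q) <- list(c("OFF", "ON", "PAUSE"), c("OFF", "ON", "PAUSE"))
  }
  Q
}

#' Initiation-rate vector of a promoter model
#'
#' @param model a [PromoterModel-class].
#' @return named numeric vector, kIni in the ON slot and zero elsewhere.
#' @export
initiationRates <- function(model) {
  stopifnot(is(model, "PromoterModel"))
  r <- rep(0, model@nStates)
  names(r) <- if (model@nStates == 2L) c("OFF", "ON") else c("OFF", "ON", "PAUSE")
  r["ON"] <- model@kIni
  r
}

#' Stationary distribution of the promoter-state chain
#'
#' @param model a [PromoterModel-class].
#' @return named numeric probability vector.
#' @export
stateProbabilities <- function(model) {
  stopifnot(is(model, "PromoterModel"))
  if (model@nStates == 2L) {
    pOn <- model@k1Plus / (model@k1Plus + model@k1Minus)
    c(OFF = 1 - pOn, ON = pOn)
  } else {
    k1p <- model@k1Plus; k1m <- model@k1Minus
    k2p <- model@k2Plus; k2m <- model@k2Minus
    z <- k1p * k2p + k1m * k2p + k1p * k2m
    c(OFF = k1m * k2p / z, ON = k1p * k2p / z, PAUSE = k1p * k2m / z)
  }
}

#' @rdname forwardDistribution
#' @export
setMethod("forwardDistribution", "PromoterModel", function(model) {
  Q <- generatorMatrix(model)
  M <- Q - diag(initiationRates(model), nrow = nrow(Q))
  e <- eigen(M)
  lam <- e$values
  if (max(abs(Im(lam))) > 1e-9 * max(abs(Re(lam))))
    stop("complex eigenvalues encountered; model outside the supported regime")
  lam <- Re(lam)
  d <- abs(outer(lam, lam, "-")); diag(d) <- Inf
  if (min(d) < 1e-10 * max(abs(lam)))
    stop("degenerate (repeated) eigenvalues; perturb the rates or use the ",
         "mixed-gamma equal-timescale limit (see gapSurvival)")
  V <- e$vectors
  w <- solve(V, rep(1, nrow(M)))
  on <- which(rownames(Q) == "ON")
  A <- Re(V[on, ] * w)
  ord <- order(lam, decreasing = TRUE)
  multiExpParams(amplitudes = A[ord], exponents = lam[ord])
})

#' @rdname simulateEventTrain
#' @export
setMethod("simulateEventTrain", "PromoterModel",
  function(model, duration, seed = NULL, nucleusId = "sim",
           startState = NULL) {
    if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
      stop("'duration' must be a single non-negative number")
    if (!is.null(seed)) set.seed(seed)
    states <- if (model@nStates == 2L) c("OFF", "ON") else c("OFF", "ON", "PAUSE")
    if (is.null(startState)) {
      p <- stateProbabilities(model)
      s <- sample(seq_along(states), 1L, prob = p)
    } else {
      s <- match(startState, states)
      if (is.na(s)) stop("unknown start state '", startState, "'")
    }
    Q <- generatorMatrix(model)
    rIni <- initiationRates(model)
    t <- 0
    events <- numeric(0)
    while (t < duration) {
      exitQ <- -Q[s, s]
      total <- exitQ + rIni[s]
      if (total <= 0) break
      t <- t + stats::rexp(1L, total)
      if (t >= duration) break
      if (stats::runif(1L) < rIni[s] / total) {
        events <- c(events, t)           # initiation, state unchanged
      } else {
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample(seq_along(states), 1L, prob = probs)
      }
    }
    initiationEventTrain(nucleusId = nucleusId, times = events,
                         window = c(0, duration))
  })

#' Construct an initiation event train
#'
#' @param nucleusId identifier.
#' @param times numeric event times in s, strictly increasing.
#' @param window numeric length-2 observation window.
#' @return an [InitiationEventTrain-class].
#' @export
initiationEventTrain <- function(nucleusId, times, window) {
  new("InitiationEventTrain", nucleusId = as.character(nucleusId),
      times = as.numeric(times), window = as.numeric(window))
}

#' @rdname derivedKinetics
#' @export
setMethod("derivedKinetics", "PromoterModel", function(model) {
  p <- stateProbabilities(model)
  if (model@nStates == 2L) {
    new("DerivedKinetics",
        tOn = 1 / model@k1Minus, tOff = 1 / model@k1Plus, tPause = NA_real_,
        pOn = unname(p["ON"]), pOff = unname(p["OFF"]), pPause = NA_real_,
        burstSize = model@kIni / model@k1Minus)
  } else {
    new("DerivedKinetics",
        tOn = 1 / (model@k1Minus + model@k2Minus),
        tOff = 1 / model@k1Plus, tPause = 1 / model@k2Plus,
        pOn = unname(p["ON"]), pOff = unname(p["OFF"]),
        pPause = unname(p["PAUSE"]),
        burstSize = model@kIni / (model@k1Minus + model@k2Minus))
  }
})

#' Serialize / read a promoter model as flat JSON
#'
#' @param model a [PromoterModel-class].
#' @param path file path.
#' @return \code{readPromoterModel} returns a [PromoterModel-class];
#'   \code{writePromoterModel} returns \code{path} invisibly.
#' @export
writePromoterModel <- function(model, path) {
  stopifnot(is(model, "PromoterModel"))
  x <- c(list(n_states = model@nStates),
         as.list(kineticRates(model)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePromoterModel
#' @export
readPromoterModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(as.integer(x$n_states), 3L))
    promoterModel(x$k1_plus, x$k1_minus, x$k_ini, x$k2_plus, x$k2_minus)
  else
    promoterModel(x$k1_plus, x$k1_minus, x$k_ini)
}

#' Write / read event trains as CSV
#'
#' Columns \code{nucleus_id}, \code{event_time_s}; window bounds are
#' stored per train in companion attributes when reading is done through
#' \code{readEventTrains} with an explicit window.
#'
#' @param trains list of [InitiationEventTrain-class] objects.
#' @param path CSV file path.
#' @param window numeric length-2 window applied to all trains on read.
#' @export
writeEventTrains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr@times)) return(NULL)
    data.frame(nucleus_id = tr@nucleusId, event_time_s = tr@times)
  }))
  if (is.null(df))
    df <- data.frame(nucleus_id = character(0), event_time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTrains
#' @export
readEventTrains <- function(path, window) {
  df <- utils::read.csv(path)
  byId <- split(df$event_time_s, df$nucleus_id)
  mapply(function(id, tt) {
    initiationEventTrain(nucleusId = id, times = sort(tt), window = window)
  }, names(byId), byId, SIMPLIFY = FALSE)
}
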