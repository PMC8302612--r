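#' Construct a fluorescence trace
#'
#' @param nucleusId identifier.
#' @param time numeric uniform frame grid (s).
#' @param intensity numeric non-negative intensities.
#' @param unit "polymerase" (calibrated) or "au" (raw).
#' @param genotype,movie character tags.
#' @return a [FluorescenceTrace-class].
#' @export
fluorescenceTrace <- function(nucleusId, time, intensity,
                              unit = "polymerase", genotype = "synthetic",
                              movie = "sim") {
  new("FluorescenceTrace", nucleusId = as.character(nucleusId),
      time = as.numeric(time), intensity = as.numeric(intensity),
      unit = unit, genotype = genotype, movie = movie)
}

#' Convolve an event train with the single-polymerase kernel
#'
#' Noiseless frame-sampled signal: the intensity at each frame is the
#' sum over initiation events of the kernel evaluated at the time since
#' that event. Events whose kernels extend past the last frame
#' contribute truncated signal.
#'
#' @param train an [InitiationEventTrain-class].
#' @param kernel a [SignalKernel-class].
#' @param frameInterval frame spacing in s (default 3.86).
#' @param frameTimes optional explicit frame grid; overrides
#'   \code{frameInterval}. Defaults to a grid covering the train window.
#' @param genotype,movie tags forwarded to the trace.
#' @return a [FluorescenceTrace-class] in polymerase units.
#' @examples
#' tr <- initiationEventTrain("n1", c(0, 10), window = c(0, 300))
#' convolveEvents(tr, signalKernel())
#' @export
convolveEvents <- function(train, kernel, frameInterval = 3.86,
                           frameTimes = NULL, genotype = "synthetic",
                           movie = "sim") {
  stopifnot(is(train, "InitiationEventTrain"), is(kernel, "SignalKernel"))
  if (is.null(frameTimes))
    frameTimes <- seq(train@window[1], train@window[2], by = frameInterval)
  ev <- train@times
  intensity <- numeric(length(frameTimes))
  if (length(ev)) {
    tau <- outer(frameTimes, ev, "-")
    tau[tau < 0] <- 0   # kernel is 0 at tau = 0, so clamping is exact
    intensity <- rowSums(matrix(kernelIntensity(kernel, as.vector(tau)),
                                nrow = length(frameTimes)))
  }
  fluorescenceTrace(train@nucleusId, frameTimes, intensity,
                    unit = "polymerase", genotype = genotype, movie = movie)
}

#' Reconstruct the signal implied by deconvolved events
#'
#' Identical contract to [convolveEvents()]; provided under the name
#' used on the deconvolution side of the pipeline.
#'
#' @inheritParams convolveEvents
#' @return a [FluorescenceTrace-class].
#' @export
reconstructSignal <- function(train, kernel, frameTimes,
                              genotype = "synthetic", movie = "sim") {
  convolveEvents(train, kernel, frameTimes = frameTimes,
                 genotype = genotype, movie = movie)
}

#' Degrade a trace with noise and a detection floor
#'
#' Adds zero-mean Gaussian noise (SD in polymerase units), clips
#' negative values to zero, and zeroes frames whose intensity does not
#' exceed the detection floor (sites with three or fewer nascent
#' transcripts are not reliably detected).
#'
#' @param trace a calibrated [FluorescenceTrace-class].
#' @param noiseSd Gaussian noise SD in polymerase units.
#' @param detectionFloor minimum detectable number of polymerases
#'   (frames with intensity <= floor are set to 0); default 3.
#' @param seed optional integer seed.
#' @return a [FluorescenceTrace-class].
#' @export
degradeTrace <- function(trace, noiseSd = 0, detectionFloor = 3,
                         seed = NULL) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!is.null(seed)) set.seed(seed)
  y <- trace@intensity
  if (noiseSd > 0) y <- y + stats::rnorm(length(y), 0, noiseSd)
  y <- pmax(y, 0)
  if (detectionFloor > 0) y[y <= detectionFloor] <- 0
  fluorescenceTrace(trace@nucleusId, trace@time, y, unit = trace@unit,
                    genotype = trace@genotype, movie = trace@movie)
}

#' Calibrate raw intensities to polymerase units
#'
#' Divides intensities by the single-molecule intensity (derived from
#' fixed-sample single-molecule FISH), flipping the unit tag from raw
#' arbitrary units to polymerase counts.
#'
#' @param trace a [FluorescenceTrace-class] in arbitrary units.
#' @param singleMoleculeIntensity a.u. per polymerase, > 0.
#' @return a calibrated [FluorescenceTrace-class].
#' @export
calibrateIntensity <- function(trace, singleMoleculeIntensity) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (!is.numeric(singleMoleculeIntensity) ||
      length(singleMoleculeIntensity) != 1L ||
      !is.finite(singleMoleculeIntensity) || singleMoleculeIntensity <= 0)
    stop("'singleMoleculeIntensity' must be a single positive number")
  fluorescenceTrace(trace@nucleusId, trace@time,
                    trace@intensity / singleMoleculeIntensity,
                    unit = "polymerase", genotype = trace@genotype,
                    movie = trace@movie)
}

#' Cohort generation settings
#'
#' @param nNuclei number of nuclei.
#' @param movieDuration movie length in s.
#' @param noiseSd Gaussian noise SD in polymerase units.
#' @param detectionFloor detection floor in polymerases (default 3).
#' @param gap a [GapParams-class] for postmitotic onset delays.
#' @param calibrationFactor a.u. per polymerase (1 keeps traces in
#'   polymerase units).
#' @param frameInterval frame spacing in s.
#' @param seed integer seed.
#' @return a list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(nNuclei = 200, movieDuration = 1800,
                         noiseSd = 0.2, detectionFloor = 3,
                         gap = gapParams(0.4, 0.3, 60),
                         calibrationFactor = 1, frameInterval = 3.86,
                         seed = 1L) {
  stopifnot(nNuclei >= 0, movieDuration > 0, noiseSd >= 0)
  structure(list(nNuclei = nNuclei, movieDuration = movieDuration,
                 noiseSd = noiseSd, detectionFloor = detectionFloor,
                 gap = gap,
                 calibrationFactor = calibrationFactor,
                 frameInterval = frameInterval, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate a synthetic cohort of nuclei
#'
#' For each nucleus: draw a postmitotic onset delay from the mixed-gamma
#' model, simulate initiation events (Gillespie) from onset to movie
#' end, convolve with the single-polymerase kernel on the common frame
#' grid, then degrade with noise and detection floor. Ground-truth
#' trains are returned alongside the traces for recovery tests.
#'
#' @param model a [PromoterModel-class].
#' @param config a [cohortConfig()] list.
#' @param kernel a [SignalKernel-class].
#' @param genotype tag applied to all traces.
#' @return list with elements \code{traces}, \code{trains} (ground
#'   truth, times on the movie clock), \code{onsets} and \code{config}.
#' @export
generateCohort <- function(model, config = cohortConfig(),
                           kernel = signalKernel(), genotype = "synthetic") {
  stopifnot(is(model, "PromoterModel"), inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$nNuclei
  onsets <- sampleGap(config$gap, n)
  frameTimes <- seq(0, config$movieDuration, by = config$frameInterval)
  traces <- vector("list", n)
  trains <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("nucleus_%03d", i)
    dur <- max(config$movieDuration - onsets[i], 0)
    tr <- simulateEventTrain(model, dur, nucleusId = id)
    train <- initiationEventTrain(id, tr@times + onsets[i],
                                  window = c(0, config$movieDuration))
    trace <- convolveEvents(train, kernel, frameTimes = frameTimes,
                            genotype = genotype)
    trace <- degradeTrace(trace, config$noiseSd, config$detectionFloor)
    if (config$calibrationFactor != 1) {
      trace <- fluorescenceTrace(id, trace@time,
                                 trace@intensity * config$calibrationFactor,
                                 unit = "au", genotype = genotype)
    }
    traces[[i]] <- trace
    trains[[i]] <- train
  }
  list(traces = traces, trains = trains, onsets = onsets, config = config)
}

#' First detected activation time of a trace
#'
#' Onset is scored at the first frame whose intensity exceeds the
#' detection floor for at least \code{minFrames} consecutive frames.
#'
#' @param trace a [FluorescenceTrace-class].
#' @param detectionFloor polymerase detection floor.
#' @param minFrames consecutive frames required (default 2).
#' @return onset time in s, or \code{NA} if never detected.
#' @export
detectOnset <- function(trace, detectionFloor = 3, minFrames = 2L) {
  stopifnot(is(trace, "FluorescenceTrace"))
  above <- trace@intensity > detectionFloor
  if (minFrames > 1L) {
    run <- stats::filter(as.numeric(above), rep(1, minFrames),
                         sides = 1)
    idx <- which(run == minFrames)
    if (!length(idx)) return(NA_real_)
    trace@time[idx[1] - minFrames + 1L]
  } else {
    idx <- which(above)
    if (!length(idx)) return(NA_real_) else trace@time[idx[1]]
  }
}

#' Write / read fluorescence traces as CSV
#'
#' Long format with columns \code{nucleus_id}, \code{time_s},
#' \code{intensity}, \code{unit}, \code{genotype}, \code{movie}.
#'
#' @param traces list of [FluorescenceTrace-class] objects.
#' @param path CSV file path.
#' @export
writeTraces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(nucleus_id = tr@nucleusId, time_s = tr@time,
               intensity = tr@intensity, unit = tr@unit,
               genotype = tr@genotype, movie = tr@movie)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$nucleus_id), function(d) {
    d <- d[order(d$time_s), ]
    fluorescenceTrace(d$nucleus_id[1], d$time_s, d$intensity,
                      unit = d$unit[1], genotype = d$genotype[1],
                      movie = d$movie[1])
  })
}
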