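#' End-to-end pipeline configuration
#'
#' Collects every stage's settings in one serializable list. All
#' field-standard constants (3.86 s frame interval, 45 bp/s elongation,
#' 30 bp grid step, 41/1292/4526 bp reporter segments, alpha = 0.6,
#' overflow ratio 2, 3-polymerase detection floor) are documented
#' defaults, never hard-coded downstream.
#'
#' @param model a [PromoterModel-class] used in synthetic mode.
#' @param genotype genotype label for pooling.
#' @param kernel a [SignalKernel-class].
#' @param stepBp deconvolution grid step (bp).
#' @param fit a [fitConfig()] list.
#' @param ga a [gaConfig()] list.
#' @param cohort a [cohortConfig()] list.
#' @param outDir output directory.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(model = promoterModel(1/24, 1/242, 1/9),
                           genotype = "synthetic",
                           kernel = signalKernel(), stepBp = 30,
                           fit = fitConfig(), ga = gaConfig(),
                           cohort = cohortConfig(), outDir = tempfile("run")) {
  structure(list(model = model, genotype = genotype, kernel = kernel,
                 stepBp = stepBp, fit = fit, ga = ga, cohort = cohort,
                 outDir = outDir),
            class = "PipelineConfig")
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  m <- config$model
  x <- list(
    model = c(list(n_states = m@nStates), as.list(kineticRates(m))),
    genotype = config$genotype,
    kernel = list(pre_len = config$kernel@preLen,
                  ms2_len = config$kernel@ms2Len,
                  post_len = config$kernel@postLen,
                  speed = config$kernel@speed,
                  retention = config$kernel@retention),
    step_bp = config$stepBp,
    fit = unclass(config$fit),
    ga = unclass(config$ga),
    cohort = c(unclass(config$cohort)[setdiff(names(config$cohort),
                                              "gap")],
               list(gap = list(p1 = config$cohort$gap@p1,
                               p2 = config$cohort$gap@p2,
                               b = config$cohort$gap@b))))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  m <- x$model
  model <- if (identical(as.integer(m$n_states), 3L))
    promoterModel(m$k1_plus, m$k1_minus, m$k_ini, m$k2_plus, m$k2_minus)
  else promoterModel(m$k1_plus, m$k1_minus, m$k_ini)
  pipelineConfig(
    model = model, genotype = x$genotype,
    kernel = signalKernel(x$kernel$pre_len, x$kernel$ms2_len,
                          x$kernel$post_len, x$kernel$speed,
                          x$kernel$retention),
    stepBp = x$step_bp,
    fit = do.call(fitConfig, x$fit),
    ga = do.call(gaConfig, x$ga),
    cohort = do.call(cohortConfig,
                     c(x$cohort[setdiff(names(x$cohort), "gap")],
                       list(gap = gapParams(x$cohort$gap$p1,
                                            x$cohort$gap$p2,
                                            x$cohort$gap$b)))))
}

#' Run the full trace-to-kinetics pipeline
#'
#' simulate (or load) -> deconvolve -> window -> waiting times ->
#' Kaplan-Meier -> multiexponential fit with state-count selection ->
#' closed-form inversion -> kinetics report. Writes events, waiting
#' times, survival, heatmap matrix (CSV), fit and kinetics reports
#' (JSON) and a log with all seeds to \code{config$outDir}.
#'
#' @param config a [pipelineConfig()] list.
#' @param traces optional list of calibrated [FluorescenceTrace-class]
#'   objects; when \code{NULL} a synthetic cohort is generated from
#'   \code{config$model}.
#' @return (invisibly) a list with the intermediate objects:
#'   \code{trains}, \code{waitingTimes}, \code{surv}, \code{fit},
#'   \code{report}, \code{outDir}.
#' @export
runPipeline <- function(config, traces = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  synthetic <- is.null(traces)
  if (synthetic) {
    cohort <- stage("simulate",
                    generateCohort(config$model, config$cohort,
                                   config$kernel, config$genotype))
    traces <- cohort$traces
  } else {
    if (!length(traces)) stop("pipeline stage 'input' failed: no traces")
  }
  speed <- config$kernel@speed
  trains <- stage("deconvolve", lapply(traces, function(tr) {
    grid <- makeGrid(c(tr@time[1], tr@time[length(tr@time)] + 1e-9),
                     stepBp = config$stepBp, speed = speed)
    deconvolveTrace(tr, config$kernel, grid, config$ga)
  }))
  residuals <- vapply(trains, function(tr) attr(tr, "residual"), numeric(1))
  sets <- stage("waiting_times", mapply(function(tr, train) {
    w <- windowTrace(tr)
    if (is.null(w)) return(NULL)
    extractWaitingTimes(train, w, genotype = config$genotype)
  }, traces, trains, SIMPLIFY = FALSE))
  pooled <- stage("pool", poolGenotype(Filter(Negate(is.null), sets)))
  surv <- stage("survival", kmSurvival(pooled))
  fit <- stage("fit", selectNumStates(surv, config$fit))
  ## grid-discretized event times tie; the approximate KS p is intended
  fit@ksP <- tryCatch(
    suppressWarnings(modifiedKsTest(pooled, fit, config$fit$ksCutoff)),
    error = function(e) NA_real_)
  report <- stage("invert", kineticsReport(fit, config$fit$overflowRatio))

  out <- config$outDir
  writeEventTrains(trains, file.path(out, "events.csv"))
  utils::write.csv(data.frame(nucleus_id = vapply(trains, nucleusId,
                                                  character(1)),
                              residual = residuals),
                   file.path(out, "residuals.csv"), row.names = FALSE)
  utils::write.csv(data.frame(delta_t_s = pooled@deltaT,
                              censored = pooled@censored,
                              genotype = pooled@genotype,
                              nucleus_id = pooled@nucleusId),
                   file.path(out, "waiting_times.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = surv@time, S = surv@surv,
                              lo = surv@lower, hi = surv@upper,
                              n_risk = surv@nRisk),
                   file.path(out, "survival.csv"), row.names = FALSE)
  utils::write.csv(binEvents(trains), file.path(out, "heatmap.csv"))
  best <- fit@best
  jsonlite::write_json(
    list(schema = "burstKinetics/fit/1",
         N = length(best@amplitudes), A = best@amplitudes,
         lambda = best@exponents, objective = fit@objective,
         accepted = fit@accepted, ks_p = fit@ksP,
         intervals = apply(errorIntervals(fit, config$fit$overflowRatio),
                           1L, as.list, simplify = FALSE)),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  writeKineticsReport(report, file.path(out, "kinetics.json"))
  writeLines(c(sprintf("burstKinetics %s",
                       as.character(utils::packageVersion("burstKinetics"))),
               sprintf("R %s", as.character(getRversion())),
               sprintf("synthetic: %s", synthetic),
               sprintf("cohort seed: %d", config$cohort$seed),
               sprintf("ga seed: %d", config$ga$seed),
               sprintf("fit seed: %d", config$fit$seed)),
             file.path(out, "log.txt"))
  invisible(list(trains = trains, waitingTimes = pooled, surv = surv,
                 fit = fit, report = report, outDir = out))
}

#' Built-in cohort presets
#'
#' \describe{
#'   \item{two_state_fast}{telegraph model in the regime of a strong
#'     TATA promoter: T_OFF = 24 s, T_ON = 242 s, one initiation per
#'     9 s.}
#'   \item{three_state_pause}{non-obligatory pause model with clearly
#'     separated timescales: T_OFF = 30 s, T_PAUSE = 400 s,
#'     ON exited every 90 s to OFF and every 80 s to PAUSE, one
#'     initiation per 9 s.}
#' }
#'
#' @param name preset name.
#' @return a [PromoterModel-class].
#' @export
presetModel <- function(name = c("two_state_fast", "three_state_pause")) {
  name <- match.arg(name)
  switch(name,
         two_state_fast = promoterModel(1/24, 1/242, 1/9),
         three_state_pause = promoterModel(1/30, 1/90, 1/9,
                                           k2Plus = 1/400, k2Minus = 1/80))
}

#' Write a preset synthetic cohort to disk
#'
#' Generates a small (n = 50) or standard (n = 200) cohort from a
#' preset model and writes trace CSVs, the ground-truth event CSV and
#' a JSON config snapshot.
#'
#' @param preset preset name, see [presetModel()].
#' @param seed integer seed.
#' @param dir output directory.
#' @param size "small" (50 nuclei) or "standard" (200 nuclei).
#' @return (invisibly) the cohort list.
#' @export
makeFixtures <- function(preset = "two_state_fast", seed = 1L,
                         dir = tempfile("fixtures"), size = "small") {
  model <- presetModel(preset)  # errors listing presets if unknown
  n <- switch(size, small = 50L, standard = 200L,
              stop("unknown size '", size, "'; use 'small' or 'standard'"))
  cfg <- cohortConfig(nNuclei = n, seed = seed)
  cohort <- generateCohort(model, cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTraces(cohort$traces, file.path(dir, "traces.csv"))
  writeEventTrains(cohort$trains, file.path(dir, "ground_truth_events.csv"))
  jsonlite::write_json(
    c(list(preset = preset, seed = seed, n_nuclei = n,
           n_states = model@nStates), as.list(kineticRates(model))),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
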