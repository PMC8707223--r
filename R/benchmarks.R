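#' Default synchronization-benchmark configuration
#'
#' Four collector devices modelled on the bench characterization: a 1 kHz
#' reference with negligible wireless latency, and three 500 Hz devices
#' whose transport latencies (means 2, 22 and 40 ms) are redrawn at every
#' cold restart. Clock drifts are tens of ppm, timestamp jitter 1 ms sd.
#'
#' @return nested list consumable by [runSyncBenchmark()].
#' @export
defaultSyncConfig <- function() {
  list(
    duration = 20,
    nSessions = 4,
    offsetInterval = 5,
    offsetNoiseSd = 2e-4,
    reference = "jetson",
    profile = list(nStrokes = 5, strokeWidth = 0.05, strokeAmplitude = 10,
                   movementWindows = c(7, 9), movementAmplitude = 5,
                   baselineNoiseSd = 0.05),
    devices = list(
      list(name = "jetson", rate = 1000, offset0 = 0, driftPpm = 0,
           jitterSd = 1e-3, latency = 0, latencySd = 0),
      list(name = "android", rate = 500, offset0 = 0.005, driftPpm = 30,
           jitterSd = 1e-3, latency = 0.002, latencySd = 0.008),
      list(name = "gtec", rate = 500, offset0 = -0.003, driftPpm = -20,
           jitterSd = 1e-3, latency = 0.022, latencySd = 0.012),
      list(name = "openbci", rate = 500, offset0 = 0.010, driftPpm = 50,
           jitterSd = 1e-3, latency = 0.040, latencySd = 0.002)
    )
  )
}

#' Read and validate a benchmark configuration file
#'
#' Config files are YAML with the same structure as [defaultSyncConfig()].
#' Schema violations raise named errors.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readBenchmarkConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateSyncConfig(cfg)
}

validateSyncConfig <- function(cfg) {
  for (f in c("duration", "nSessions", "devices", "profile"))
    stopIfNot(!is.null(cfg[[f]]), "config field '%s' is missing", f)
  stopIfNot(cfg$duration > 0, "config field 'duration' must be positive")
  stopIfNot(cfg$nSessions >= 1, "config field 'nSessions' must be >= 1")
  for (i in seq_along(cfg$devices)) {
    d <- cfg$devices[[i]]
    for (f in c("name", "rate"))
      stopIfNot(!is.null(d[[f]]), "device %d: field '%s' is missing", i, f)
    stopIfNot(d$rate > 0, "device '%s': rate must be positive", d$name)
  }
  cfg$offsetInterval <- cfg$offsetInterval %||% 5
  cfg$offsetNoiseSd <- cfg$offsetNoiseSd %||% 2e-4
  cfg$reference <- cfg$reference %||% cfg$devices[[1]]$name
  cfg
}

configDevices <- function(cfg) {
  list(
    devices = lapply(cfg$devices, function(d)
      deviceSpec(d$name, nominalRate = d$rate,
                 lossRate = d$lossRate %||% 0,
                 lossRunMean = d$lossRunMean %||% 5)),
    clocks = lapply(cfg$devices, function(d)
      clockModel(offset0 = d$offset0 %||% 0, driftPpm = d$driftPpm %||% 0,
                 jitterSd = d$jitterSd %||% 0,
                 transportLatency = d$latency %||% 0,
                 transportLatencySd = d$latencySd %||% 0))
  )
}

configProfile <- function(cfg) {
  p <- cfg$profile
  mw <- p$movementWindows %||% numeric()
  if (length(mw)) mw <- matrix(unlist(mw), ncol = 2, byrow = TRUE)
  else mw <- matrix(numeric(), ncol = 2)
  perturbationProfile(
    nStrokes = p$nStrokes %||% 3L,
    strokeWidth = p$strokeWidth %||% 0.05,
    strokeAmplitude = p$strokeAmplitude %||% 10,
    movementWindows = mw,
    movementBandwidth = p$movementBandwidth %||% 8,
    movementAmplitude = p$movementAmplitude %||% (p$strokeAmplitude %||% 10) / 2,
    baselineNoiseSd = p$baselineNoiseSd %||% 0.05)
}

#' Run the end-to-end synchronization benchmark
#'
#' Simulates \code{nSessions} cold restarts (transport latencies redrawn
#' each time), synchronizes every session (clock fit, remap, dejitter),
#' estimates all pairwise lags from the shared perturbations, builds the
#' offset matrix, and compensates the first session to measure residual
#' lags. All randomness flows from \code{seed}. When \code{outDir} is given,
#' CSV reports (offset table, ground-truth-vs-recovered errors, residuals)
#' and a plain-text summary embedding the seed and a config hash are
#' written.
#'
#' @param config list as from [defaultSyncConfig()] or
#'   [readBenchmarkConfig()].
#' @param seed integer master seed.
#' @param outDir optional report directory.
#' @return list with \code{matrix} ([OffsetMatrix-class]), \code{lagMatrices}
#'   (per session), \code{truthMs} (mean ground-truth offsets),
#'   \code{errorsMs}, \code{residualMs} (post-compensation lag matrix) and
#'   \code{timings} (per-stage seconds).
#' @export
runSyncBenchmark <- function(config = defaultSyncConfig(), seed = 1L,
                             outDir = NULL) {
  config <- validateSyncConfig(config)
  dc <- configDevices(config)
  profile <- configProfile(config)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  lagMatrices <- vector("list", config$nSessions)
  truths <- vector("list", config$nSessions)
  firstSession <- NULL
  t0 <- tic()
  for (s in seq_len(config$nSessions)) {
    sess <- simulateSession(dc$devices, dc$clocks, profile,
                            duration = config$duration,
                            seed = childSeed(seed, paste0("session", s)),
                            offsetInterval = config$offsetInterval,
                            offsetNoiseSd = config$offsetNoiseSd)
    sess <- synchronizeSession(sess)
    lagMatrices[[s]] <- sessionLagMatrix(sess)
    truths[[s]] <- groundTruth(sess)$offsetMs
    if (s == 1) firstSession <- sess
  }
  timings["simulate_estimate"] <- tic() - t0
  rates <- vapply(dc$devices, function(d) d@nominalRate, numeric(1))
  names(rates) <- vapply(dc$devices, function(d) d@name, character(1))
  mat <- buildOffsetMatrix(lagMatrices, rates)
  truthMs <- Reduce("+", truths) / length(truths)
  errorsMs <- meanMs(mat) - truthMs
  t0 <- tic()
  # transport latencies are redrawn at every startup, so compensation uses
  # the session's own calibration (the across-session matrix reports the
  # platform's typical offsets and their restart variability)
  sessMat <- suppressWarnings(buildOffsetMatrix(lagMatrices[1], rates))
  comp <- compensateStreams(firstSession, sessMat, config$reference)
  residualMs <- sessionLagMatrix(comp)
  timings["compensate_verify"] <- tic() - t0
  out <- list(matrix = mat, lagMatrices = lagMatrices, truthMs = truthMs,
              errorsMs = errorsMs, residualMs = residualMs,
              seed = seed, timings = timings)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeOffsetReport(mat, file.path(outDir, "offsets.csv"))
    utils::write.csv(round(errorsMs, 3), file.path(outDir, "errors_ms.csv"))
    utils::write.csv(round(residualMs, 3),
                     file.path(outDir, "residuals_ms.csv"))
    cfgHash <- sum(utf8ToInt(paste(deparse(config), collapse = "")))
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("config-hash: %d", cfgHash),
                 sprintf("sessions: %d", config$nSessions),
                 sprintf("stage timings (s): %s",
                         paste(names(timings), round(timings, 2),
                               sep = "=", collapse = ", "))),
               file.path(outDir, "summary.txt"))
  }
  out
}

taskFeaturePlan <- function(task) {
  switch(task,
    eyes = list(a = "closed", b = "open", kind = "psd", channel = "Oz",
                band = c(8, 12)),
    motor = list(a = "move", b = "rest", kind = "psd", channel = "C3",
                 band = c(8, 12)),
    ssvep = list(a = "ssvep_5", b = "rest", kind = "psd", channel = "Oz",
                 band = c(9.5, 10.5)),
    oddball = list(a = "target", b = "nontarget", kind = "erp",
                   channel = "Cz", window = c(0.25, 0.55)),
    stop("unknown task '", task, "'", call. = FALSE))
}

#' Run the EEG validation pipeline end-to-end
#'
#' For each task and device profile: synthesize the task recording, inject
#' artifacts, preprocess (common-average reference, 1-30 Hz), project out
#' blinks, epoch, apply the rejection rules, compute the task's per-trial
#' feature (PSD peak or ERP peak), compare conditions bin-by-bin, and
#' compute the trial-subsampling power curve. All randomness flows from
#' \code{seed}; the same protocol realization is shared across profiles so
#' they are compared on identical trial schedules.
#'
#' @param tasks subset of c("eyes", "motor", "ssvep", "oddball").
#' @param profiles device profile names (see [deviceProfile()]).
#' @param effects an [EffectSpec-class].
#' @param seed integer master seed.
#' @param nPerm permutations per power-curve point.
#' @param nGrid trial-count grid (NULL = spread over the available trials).
#' @param blinkPeriodS free-blinking period length, seconds.
#' @param outDir optional report directory (rejection counts and power
#'   tables as CSV).
#' @return nested list \code{res[[task]][[profile]]} with elements
#'   \code{nTrials}, \code{rejectionCounts}, \code{comparison},
#'   \code{power} ([PowerCurve-class]) and \code{featureSummary}.
#' @export
runEegValidation <- function(tasks = c("eyes", "ssvep", "oddball"),
                             profiles = c("egi_like", "biohub_like"),
                             effects = effectSpec(), seed = 1L,
                             nPerm = 200L, nGrid = NULL,
                             blinkPeriodS = 60, outDir = NULL) {
  res <- list()
  rows <- list()
  powRows <- list()
  bad <- setdiff(tasks, c("eyes", "motor", "ssvep", "oddball"))
  if (length(bad))
    stop("unknown task(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (task in tasks) {
    protocol <- taskProtocol(task, seed = childSeed(seed, task),
                             blinkPeriodS = blinkPeriodS)
    plan <- taskFeaturePlan(task)
    for (prof in profiles) {
      rec <- synthTaskRecording(protocol, effects, deviceProfile(prof),
                                seed = childSeed(seed, paste(task, "synth")))
      rec <- injectArtifacts(rec, effects,
                             seed = childSeed(seed, paste(task, prof, "art")))
      # SSP before re-referencing: the projector then captures the blink's
      # true front-to-back gradient rather than its average-reference image
      rec <- withCallingHandlers(blinkProject(rec),
        warning = function(w) invokeRestart("muffleWarning"))
      rec <- preprocess(rec, mode = "validation")
      ep <- rejectEpochs(extractEpochs(rec, task))
      featA <- if (plan$kind == "psd")
        trialPsdPeak(ep, plan$a, plan$channel, plan$band)
      else trialErpPeak(ep, plan$a, plan$channel, plan$window)
      featB <- if (plan$kind == "psd")
        trialPsdPeak(ep, plan$b, plan$channel, plan$band)
      else trialErpPeak(ep, plan$b, plan$channel, plan$window)
      grid <- nGrid %||% unique(pmax(2, round(seq(2,
        min(length(featA), length(featB)), length.out = 8))))
      pw <- powerCurve(featA, featB, grid, nPerm = nPerm,
                       seed = childSeed(seed, paste(task, prof, "pow")))
      cmpTest <- stats::t.test(featA, featB)
      res[[task]][[prof]] <- list(
        nTrials = c(a = length(featA), b = length(featB)),
        rejectionCounts = ep@meta$rejectionCounts,
        comparison = cmpTest,
        power = pw,
        featureSummary = c(meanA = mean(featA), meanB = mean(featB)))
      rows[[length(rows) + 1]] <- data.frame(
        task = task, profile = prof,
        as.data.frame(ep@meta$rejectionCounts))
      powRows[[length(powRows) + 1]] <- data.frame(
        task = task, profile = prof, n = powerGrid(pw),
        proportion = powerProportion(pw), n80 = n80(pw))
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(do.call(rbind, rows),
                     file.path(outDir, "rejection_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, powRows),
                     file.path(outDir, "power_curves.csv"), row.names = FALSE)
  }
  res
}
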