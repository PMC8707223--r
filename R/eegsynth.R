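#' EEG montage used by the synthetic recordings
#'
#' The seven dry-electrode sites of the wearable headset.
#' @export
EEG_CHANNELS <- c("Fpz", "Fz", "Cz", "Pz", "Oz", "C3", "C4")

#' Effect specification for the synthetic EEG generator
#'
#' Amplitudes are in microvolts on the scalp. Defaults are typical adult
#' values for the features the validation tasks probe: a 3-4x occipital
#' alpha reactivity, a 50% sensorimotor power drop during movement, a few-uV
#' steady-state response and a mid-single-digit-uV P300 peaking around
#' 300 ms.
#'
#' @slot alphaOpenUv,alphaClosedUv occipital alpha amplitude (uV) per state;
#'   closed must exceed open for a positive-reactivity subject.
#' @slot smrUv sensorimotor (10-20 Hz) rhythm RMS at C3/C4/Cz, uV.
#' @slot erdFraction relative sensorimotor band-power reduction during
#'   movement (0.5 = -3 dB).
#' @slot ssvepUv steady-state response amplitude at the alternation
#'   frequency, uV.
#' @slot p300Uv P300 peak amplitude, uV.
#' @slot p300LatencyMs P300 peak latency, ms, inside [250, 400].
#' @slot backgroundNoiseUv broadband (1/f + white) background RMS, uV.
#' @slot blinkRateHz blink rate; \code{blinkAmplitudeUv} the Fpz peak.
#' @slot blinkAmplitudeUv blink peak amplitude at Fpz, uV.
#' @slot nLostRuns,lostRunLength lost-sample injection: number of runs and
#'   run length in samples.
#' @slot nAmpArtifacts,ampArtifactUv amplitude-artifact injection.
#' @slot nDriftSegments,driftAmplitudeUv,driftDurationS linear-drift injection.
#' @exportClass EffectSpec
setClass("EffectSpec",
  representation(
    alphaOpenUv = "numeric", alphaClosedUv = "numeric", smrUv = "numeric",
    erdFraction = "numeric", ssvepUv = "numeric", p300Uv = "numeric",
    p300LatencyMs = "numeric", backgroundNoiseUv = "numeric",
    blinkRateHz = "numeric", blinkAmplitudeUv = "numeric",
    nLostRuns = "integer", lostRunLength = "integer",
    nAmpArtifacts = "integer", ampArtifactUv = "numeric",
    nDriftSegments = "integer", driftAmplitudeUv = "numeric",
    driftDurationS = "numeric"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (object@alphaClosedUv <= object@alphaOpenUv)
    msg <- c(msg, "alphaClosedUv must exceed alphaOpenUv (positive reactivity)")
  if (object@p300LatencyMs < 250 || object@p300LatencyMs > 400)
    msg <- c(msg, "p300LatencyMs must lie in [250, 400] ms")
  if (object@erdFraction < 0 || object@erdFraction >= 1)
    msg <- c(msg, "erdFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname EffectSpec-class
#' @param alphaOpenUv,alphaClosedUv,smrUv,erdFraction,ssvepUv,p300Uv,p300LatencyMs,backgroundNoiseUv,blinkRateHz,blinkAmplitudeUv,nLostRuns,lostRunLength,nAmpArtifacts,ampArtifactUv,nDriftSegments,driftAmplitudeUv,driftDurationS see slot docs.
#' @return an [EffectSpec-class].
#' @export
effectSpec <- function(alphaOpenUv = 2, alphaClosedUv = 8, smrUv = 12,
                       erdFraction = 0.5, ssvepUv = 5, p300Uv = 5,
                       p300LatencyMs = 300, backgroundNoiseUv = 8,
                       blinkRateHz = 0.2, blinkAmplitudeUv = 120,
                       nLostRuns = 3L, lostRunLength = 30L,
                       nAmpArtifacts = 2L, ampArtifactUv = 80,
                       nDriftSegments = 1L, driftAmplitudeUv = 45,
                       driftDurationS = 5) {
  new("EffectSpec", alphaOpenUv = alphaOpenUv, alphaClosedUv = alphaClosedUv,
      smrUv = smrUv, erdFraction = erdFraction, ssvepUv = ssvepUv,
      p300Uv = p300Uv, p300LatencyMs = p300LatencyMs,
      backgroundNoiseUv = backgroundNoiseUv, blinkRateHz = blinkRateHz,
      blinkAmplitudeUv = blinkAmplitudeUv, nLostRuns = as.integer(nLostRuns),
      lostRunLength = as.integer(lostRunLength),
      nAmpArtifacts = as.integer(nAmpArtifacts), ampArtifactUv = ampArtifactUv,
      nDriftSegments = as.integer(nDriftSegments),
      driftAmplitudeUv = driftAmplitudeUv, driftDurationS = driftDurationS)
}

#' Device noise profile
#'
#' \code{biohub_like} models the wearable dry-electrode system: strictly
#' higher broadband noise than the lab-grade \code{egi_like} profile, and
#' wireless transport losses enabled.
#'
#' @slot name profile name.
#' @slot noiseMultiplier broadband noise scale factor.
#' @slot lossEnabled whether transport losses are injected.
#' @exportClass DeviceProfile
setClass("DeviceProfile",
  representation(name = "character", noiseMultiplier = "numeric",
                 lossEnabled = "logical"))

#' @rdname DeviceProfile-class
#' @param name "egi_like" or "biohub_like" (or any custom name).
#' @param noiseMultiplier,lossEnabled override the profile defaults.
#' @return a [DeviceProfile-class].
#' @export
deviceProfile <- function(name = c("egi_like", "biohub_like"),
                          noiseMultiplier = NULL, lossEnabled = NULL) {
  name <- name[1]
  defaults <- switch(name,
    egi_like = list(mult = 1, loss = FALSE),
    biohub_like = list(mult = 1.5, loss = TRUE),
    list(mult = 1, loss = FALSE))
  new("DeviceProfile", name = name,
      noiseMultiplier = noiseMultiplier %||% defaults$mult,
      lossEnabled = lossEnabled %||% defaults$loss)
}

#' Generate an oddball stimulus sequence
#'
#' Non-target count follows the task's printed pairing (10 targets with 60
#' non-targets, 12 with 72), i.e. one target per six non-targets:
#' \code{nonTargets = nTargets / ratio} with default \code{ratio = 1/6}.
#' The nominal "1/5" target/non-target ratio quoted for the task is
#' inconsistent with that pairing and is not used. Order is randomized with
#' no two consecutive targets (targets are placed into distinct gaps of the
#' non-target sequence).
#'
#' @param nTargets number of target stimuli (>= 1).
#' @param ratio target:non-target ratio (default 1/6 per the pairing rule).
#' @param seed integer seed.
#' @return character vector of labels ("target"/"nontarget").
#' @export
genOddballSequence <- function(nTargets, ratio = 1 / 6, seed = 1L) {
  stopIfNot(nTargets >= 1, "need at least one target")
  stopIfNot(ratio > 0 && ratio < 1, "ratio must lie in (0, 1)")
  nNon <- nTargets / ratio
  if (abs(nNon - round(nNon)) > 1e-9)
    warning("ratio yields a non-integer non-target count; rounding",
            call. = FALSE)
  nNon <- round(nNon)
  stopIfNot(nNon + 1 >= nTargets,
            "cannot avoid consecutive targets with so few non-targets")
  withSeed(seed, {
    gaps <- sort(sample.int(nNon + 1, nTargets))  # distinct gaps: no two adjacent
    lab <- character()
    for (g in seq_len(nNon + 1)) {
      if (g %in% gaps) lab <- c(lab, "target")
      if (g <= nNon) lab <- c(lab, "nontarget")
    }
    lab
  })
}

#' Generate one BCI menu-carousel run
#'
#' Six menu icons, each repeated three times, one icon designated the target:
#' an 18-trial run with 3 target and 15 non-target appearances, randomly
#' ordered.
#'
#' @param nIcons number of menu icons.
#' @param nReps repetitions per icon.
#' @param seed integer seed.
#' @return data.frame with columns \code{icon} and \code{label}.
#' @export
bciRunSequence <- function(nIcons = 6L, nReps = 3L, seed = 1L) {
  withSeed(seed, {
    icons <- rep(seq_len(nIcons), nReps)
    icons <- sample(icons)
    target <- sample.int(nIcons, 1)
    data.frame(icon = icons,
               label = ifelse(icons == target, "target", "nontarget"))
  })
}

#' Build a task protocol (event schedule)
#'
#' Encodes the validation task designs: eyes open/closed alternation (10
#' repetitions of 5 s open / 5 s closed), motor clutching (25 repetitions,
#' 4 s move, rest uniform 8-12 s), pattern-reversal SSVEP (3 runs of 10 s per
#' modulation frequency 5 and 6 Hz, 7 s rest) and the visual oddball (5 runs,
#' 10-12 targets each, 200 ms stimulus + 400 ms ISI, non-targets per the
#' pairing rule). Every session starts with a free-blinking period used for
#' blink identification.
#'
#' @param task one of "eyes", "motor", "ssvep", "oddball".
#' @param seed integer seed (rest durations, target counts, orders).
#' @param blinkPeriodS duration of the initial free-blinking period, seconds
#'   (default 60).
#' @return list with elements \code{task}, \code{events} (data.frame onset,
#'   label, duration), \code{duration}, \code{blinkPeriod}.
#' @export
taskProtocol <- function(task = c("eyes", "motor", "ssvep", "oddball"),
                         seed = 1L, blinkPeriodS = 60) {
  task <- match.arg(task)
  t0 <- blinkPeriodS + 5
  ev <- withSeed(childSeed(seed, paste0("protocol-", task)), {
    switch(task,
      eyes = {
        onsets <- t0 + seq(0, by = 5, length.out = 20)
        data.frame(onset = onsets,
                   label = rep(c("open", "closed"), 10),
                   duration = 5)
      },
      motor = {
        onset <- t0
        rows <- vector("list", 50)
        for (r in 1:25) {
          rows[[2 * r - 1]] <- data.frame(onset = onset, label = "move",
                                          duration = 4)
          onset <- onset + 4
          rest <- stats::runif(1, 8, 12)
          rows[[2 * r]] <- data.frame(onset = onset, label = "rest",
                                      duration = rest)
          onset <- onset + rest
        }
        do.call(rbind, rows)
      },
      ssvep = {
        onset <- t0
        rows <- list()
        for (f in c(5, 6)) for (r in 1:3) {
          rows[[length(rows) + 1]] <-
            data.frame(onset = onset, label = sprintf("ssvep_%d", f),
                       duration = 10)
          rows[[length(rows) + 1]] <-
            data.frame(onset = onset + 10, label = "rest", duration = 7)
          onset <- onset + 10 + 7
        }
        do.call(rbind, rows)
      },
      oddball = {
        onset <- t0
        rows <- list()
        for (r in 1:5) {
          nT <- sample(10:12, 1)
          lab <- genOddballSequence(nT, seed = childSeed(seed,
                                                         paste0("run", r)))
          rows[[r]] <- data.frame(onset = onset + 0.6 * (seq_along(lab) - 1),
                                  label = lab, duration = 0.2)
          onset <- onset + 0.6 * length(lab) + 5
        }
        do.call(rbind, rows)
      })
  })
  last <- max(ev$onset + ev$duration)
  list(task = task, events = ev, duration = ceiling(last + 2),
       blinkPeriod = c(0, blinkPeriodS))
}

# 1/f ("pink", power slope -1) noise of length n, unit variance.
pinkNoise <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited gaussian noise (zero-phase filtered), unit RMS.
bandNoise <- function(n, band, sfreq) {
  bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2000))[1001:(1000 + n)]
  x / stats::sd(x)
}

# Smooth a binary on/off envelope with cosine ramps of rampN samples.
smoothEnvelope <- function(env, rampN) {
  if (rampN < 2) return(env)
  k <- 0.5 - 0.5 * cos(pi * seq_len(rampN) / (rampN + 1))
  k <- c(k, rev(k))
  k <- k / sum(k)
  as.numeric(stats::filter(c(rep(env[1], rampN), env, rep(env[length(env)], rampN)),
                           k, sides = 2))[(rampN + 1):(rampN + length(env))]
}

#' Synthesize a task recording
#'
#' Seven channels at 500 Hz. Background activity is 1/f (power slope -1)
#' plus white noise, scaled by the device profile's noise multiplier; the
#' task feature is synthesized at the physiologically correct channels:
#' occipital alpha reactivity at Oz (half-weight Pz), sensorimotor rhythm
#' with multiplicative movement attenuation at C3/C4/Cz, the steady-state
#' response at twice the modulation frequency at Oz, and a P300 on target
#' stimuli at Cz (0.8-weight Pz) plus a small early visual response to every
#' stimulus at Oz. Event markers carry condition labels and onsets.
#' Deterministic given \code{seed}; equal seeds with different device
#' profiles reuse the identical noise realization, scaled.
#'
#' @param protocol from [taskProtocol()].
#' @param effects an [EffectSpec-class].
#' @param device a [DeviceProfile-class].
#' @param seed integer seed.
#' @param sfreq sampling rate, Hz (default 500).
#' @return a [Recording-class].
#' @export
synthTaskRecording <- function(protocol, effects = effectSpec(),
                               device = deviceProfile("biohub_like"),
                               seed = 1L, sfreq = 500) {
  n <- round(protocol$duration * sfreq)
  t <- seq(0, by = 1 / sfreq, length.out = n)
  nch <- length(EEG_CHANNELS)
  ev <- protocol$events
  data <- withSeed(childSeed(seed, "background"), {
    tot <- effects@backgroundNoiseUv
    m <- matrix(0, nch, n)
    for (ch in seq_len(nch))
      m[ch, ] <- sqrt(0.8) * tot * pinkNoise(n) +
        sqrt(0.2) * tot * stats::rnorm(n)
    m * device@noiseMultiplier
  })
  rownames(data) <- EEG_CHANNELS
  addTo <- function(chan, weight, sig) {
    i <- match(chan, EEG_CHANNELS)
    data[i, ] <<- data[i, ] + weight * sig
  }
  withSeed(childSeed(seed, "features"), {
    ramp <- round(0.2 * sfreq)
    if (protocol$task == "eyes") {
      env <- rep(effects@alphaOpenUv, n)
      for (k in which(ev$label == "closed")) {
        idx <- t >= ev$onset[k] & t < ev$onset[k] + ev$duration[k]
        env[idx] <- effects@alphaClosedUv
      }
      env <- smoothEnvelope(env, ramp)
      alpha <- env * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
      addTo("Oz", 1, alpha)
      addTo("Pz", 0.5, alpha)
    } else if (protocol$task == "motor") {
      gain <- rep(1, n)
      for (k in which(ev$label == "move")) {
        idx <- t >= ev$onset[k] & t < ev$onset[k] + ev$duration[k]
        gain[idx] <- sqrt(1 - effects@erdFraction)
      }
      gain <- smoothEnvelope(gain, ramp)
      for (chan in c("C3", "C4", "Cz")) {
        smr <- effects@smrUv * bandNoise(n, c(10, 20), sfreq)
        addTo(chan, 1, smr * gain)
      }
    } else if (protocol$task == "ssvep") {
      for (k in which(startsWith(ev$label, "ssvep_"))) {
        fmod <- as.numeric(sub("ssvep_", "", ev$label[k]))
        idx <- which(t >= ev$onset[k] & t < ev$onset[k] + ev$duration[k])
        env <- smoothEnvelope(c(rep(1, length(idx))), ramp)
        sig <- effects@ssvepUv * env *
          sin(2 * pi * (2 * fmod) * t[idx] + stats::runif(1, 0, 2 * pi))
        data[match("Oz", EEG_CHANNELS), idx] <-
          data[match("Oz", EEG_CHANNELS), idx] + sig
        data[match("Pz", EEG_CHANNELS), idx] <-
          data[match("Pz", EEG_CHANNELS), idx] + 0.4 * sig
      }
    } else if (protocol$task == "oddball") {
      lat <- effects@p300LatencyMs / 1000
      kern <- function(tt) exp(-0.5 * ((tt - lat) / 0.06)^2)
      vis <- function(tt) exp(-0.5 * ((tt - 0.12) / 0.025)^2)
      for (k in seq_len(nrow(ev))) {
        idx <- which(t >= ev$onset[k] & t < ev$onset[k] + 0.8)
        tt <- t[idx] - ev$onset[k]
        addv <- 1.0 * vis(tt)
        data[match("Oz", EEG_CHANNELS), idx] <-
          data[match("Oz", EEG_CHANNELS), idx] + addv
        if (ev$label[k] == "target") {
          p <- effects@p300Uv * kern(tt)
          data[match("Cz", EEG_CHANNELS), idx] <-
            data[match("Cz", EEG_CHANNELS), idx] + p
          data[match("Pz", EEG_CHANNELS), idx] <-
            data[match("Pz", EEG_CHANNELS), idx] + 0.8 * p
        }
      }
    }
  })
  new("Recording", data = data, channels = EEG_CHANNELS, sfreq = sfreq,
      events = ev[, c("onset", "label")], lostMask = rep(FALSE, n),
      blinkPeriod = protocol$blinkPeriod,
      injectionLog = data.frame(kind = character(), start = numeric(),
                                end = numeric(), channel = character()),
      meta = list(task = protocol$task, profile = device@name, seed = seed))
}

# Stereotyped biphasic blink waveform over [0, 0.3] s, unit peak.
blinkKernel <- function(tt) {
  w <- exp(-0.5 * ((tt - 0.10) / 0.04)^2) - 0.35 * exp(-0.5 * ((tt - 0.22) / 0.06)^2)
  w / max(w)
}

# Front-to-back blink gradient over the montage.
BLINK_GRADIENT <- c(Fpz = 1, Fz = 0.6, Cz = 0.35, Pz = 0.15, Oz = 0.05,
                    C3 = 0.3, C4 = 0.3)

#' Inject artifacts into a recording
#'
#' Adds the stressors each rejection rule is meant to catch: stereotyped
#' 300 ms biphasic blinks (largest at Fpz, front-to-back gradient),
#' lost-sample runs marked in the lost mask, amplitude artifacts exceeding
#' the +/-50 uV bound, and near-linear drift ramps. Every injection is
#' recorded in the returned recording's injection log (ground truth for
#' rejection tests). Loss injection honours the device profile used at
#' synthesis time: it is skipped when \code{meta$profile} is a loss-free
#' profile unless times are given explicitly.
#'
#' @param recording a [Recording-class].
#' @param effects an [EffectSpec-class] (rates, counts, amplitudes).
#' @param seed integer seed.
#' @param blinkTimes,lossAt,ampAt,driftAt optional explicit start times
#'   (seconds); defaults are drawn randomly.
#' @return the recording with artifacts added and the injection log filled.
#' @export
injectArtifacts <- function(recording, effects = effectSpec(), seed = 1L,
                            blinkTimes = NULL, lossAt = NULL, ampAt = NULL,
                            driftAt = NULL) {
  sfreq <- recording@sfreq
  n <- ncol(recording@data)
  dur <- n / sfreq
  log <- recording@injectionLog
  withSeed(childSeed(seed, "artifacts"), {
    # blinks
    if (is.null(blinkTimes) && effects@blinkRateHz > 0) {
      nb <- stats::rpois(1, effects@blinkRateHz * dur)
      blinkTimes <- sort(stats::runif(nb, 0, dur - 0.35))
    }
    kt <- seq(0, 0.3, by = 1 / sfreq)
    kern <- blinkKernel(kt)
    for (b in blinkTimes %||% numeric()) {
      i0 <- round(b * sfreq) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      if (max(idx) > n) next
      for (ch in seq_along(recording@channels)) {
        g <- BLINK_GRADIENT[recording@channels[ch]]
        if (is.na(g)) g <- 0.1
        recording@data[ch, idx] <- recording@data[ch, idx] +
          g * effects@blinkAmplitudeUv * kern
      }
      log <- rbind(log, data.frame(kind = "blink", start = b, end = b + 0.3,
                                   channel = "Fpz"))
    }
    # lost runs
    lossFree <- identical(recording@meta$profile, "egi_like")
    if (is.null(lossAt) && !lossFree && effects@nLostRuns > 0)
      lossAt <- stats::runif(effects@nLostRuns, 0, dur - 1)
    for (ls in lossAt %||% numeric()) {
      i0 <- round(ls * sfreq) + 1L
      idx <- i0:min(n, i0 + effects@lostRunLength - 1L)
      recording@lostMask[idx] <- TRUE
      recording@data[, idx] <- 0
      log <- rbind(log, data.frame(kind = "loss", start = ls,
                                   end = ls + effects@lostRunLength / sfreq,
                                   channel = "all"))
    }
    # amplitude artifacts (exceed the +/-50 uV validation bound)
    if (is.null(ampAt) && effects@nAmpArtifacts > 0)
      ampAt <- stats::runif(effects@nAmpArtifacts, 0, dur - 1)
    bumpN <- round(0.3 * sfreq)
    bump <- hannWindow(bumpN)
    for (as0 in ampAt %||% numeric()) {
      i0 <- round(as0 * sfreq) + 1L
      idx <- i0:(i0 + bumpN - 1L)
      if (max(idx) > n) next
      ch <- sample(seq_along(recording@channels), 1)
      recording@data[ch, idx] <- recording@data[ch, idx] +
        effects@ampArtifactUv * bump
      log <- rbind(log, data.frame(kind = "amplitude", start = as0,
                                   end = as0 + bumpN / sfreq,
                                   channel = recording@channels[ch]))
    }
    # linear drift segments
    if (is.null(driftAt) && effects@nDriftSegments > 0)
      driftAt <- stats::runif(effects@nDriftSegments, 0,
                              max(0.1, dur - effects@driftDurationS - 1))
    # saturation-like drift: the electrode signal collapses onto a near-
    # linear ramp (a small residual of the original activity remains)
    for (ds in driftAt %||% numeric()) {
      len <- round(effects@driftDurationS * sfreq)
      i0 <- round(ds * sfreq) + 1L
      idx <- i0:min(n, i0 + len - 1L)
      ramp <- seq(0, effects@driftAmplitudeUv, length.out = length(idx))
      ch <- sample(seq_along(recording@channels), 1)
      recording@data[ch, idx] <- ramp + 0.1 * recording@data[ch, idx]
      log <- rbind(log, data.frame(kind = "drift", start = ds,
                                   end = ds + length(idx) / sfreq,
                                   channel = recording@channels[ch]))
    }
  })
  recording@injectionLog <- log
  recording
}
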