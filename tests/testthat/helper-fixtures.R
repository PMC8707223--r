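# Shared fixture builders. Everything is generated in code at test time.

# An EpochSet built directly from a trials x channels x time array.
makeEpochs <- function(dat, sfreq = 500, times = NULL, labels = NULL,
                       channels = NULL, lostMask = NULL) {
  d <- dim(dat)
  times <- times %||% seq(0, by = 1 / sfreq, length.out = d[3])
  new("EpochSet",
      data = dat, times = times,
      channels = channels %||% paste0("ch", seq_len(d[2])),
      sfreq = sfreq,
      labels = labels %||% rep("a", d[1]),
      lostMask = lostMask %||% matrix(FALSE, d[1], d[3]),
      rejected = rep(FALSE, d[1]),
      rejectReason = rep(NA_character_, d[1]),
      meta = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A quick two-device session fixture with known clock parameters.
tinySession <- function(seed = 1L, duration = 12,
                        lat = c(0, 0.040), jitterSd = 1e-3,
                        driftPpm = c(0, 50), offset0 = c(0, 0.002),
                        lossRate = c(0, 0), offsetNoiseSd = 2e-4) {
  devs <- list(deviceSpec("ref", 1000, lossRate = lossRate[1]),
               deviceSpec("dev", 500, lossRate = lossRate[2]))
  clks <- list(clockModel(offset0[1], driftPpm[1], jitterSd, lat[1], 0),
               clockModel(offset0[2], driftPpm[2], jitterSd, lat[2], 0))
  prof <- perturbationProfile(nStrokes = 4L, movementWindows = c(7, 9))
  simulateSession(devs, clks, prof, duration = duration, seed = seed,
                  offsetNoiseSd = offsetNoiseSd)
}
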