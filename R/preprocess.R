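#' Preprocess a recording
#'
#' Validation mode: common-average reference, then zero-phase band-pass
#' 1-30 Hz. BCI mode: no re-referencing (ear-referenced montage) and
#' band-pass 0.1-30 Hz. The band-pass is a cascade of order-4 Butterworth
#' high-pass and low-pass filters applied forward-backward
#' (\code{signal::filtfilt}), so ERP latencies are preserved.
#'
#' @param recording a [Recording-class].
#' @param mode "validation" or "bci".
#' @param band optional (low, high) Hz override of the mode's default band.
#' @return the filtered [Recording-class].
#' @export
preprocess <- function(recording, mode = c("validation", "bci"), band = NULL) {
  mode <- match.arg(mode)
  if (is.null(band)) band <- if (mode == "validation") c(1, 30) else c(0.1, 30)
  nyq <- recording@sfreq / 2
  stopIfNot(band[1] > 0 && band[2] < nyq && band[1] < band[2],
            "band (%g, %g) Hz must lie inside (0, Nyquist = %g) Hz",
            band[1], band[2], nyq)
  x <- recording@data
  if (mode == "validation") {
    stopIfNot(nrow(x) >= 2, "common-average reference needs >= 2 channels")
    x <- sweep(x, 2, colMeans(x), "-")
  }
  hp <- signal::butter(4, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  for (ch in seq_len(nrow(x)))
    x[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x[ch, ]))
  recording@data <- x
  recording@meta$preprocessed <- list(mode = mode, band = band)
  recording
}

#' Remove the blink subspace by signal-space projection
#'
#' Blinks are detected on Fpz (robust z-score above \code{zThresh} against a
#' median/MAD baseline, grouped into +/- \code{halfWindow} windows around each
#' excursion). The first principal component of the concatenated blink
#' segments across channels is projected out of the whole recording. The
#' free-blinking period, when the recording has one, anchors the detection
#' threshold.
#'
#' @param recording a [Recording-class] with an Fpz channel.
#' @param zThresh robust z threshold (default 3).
#' @param halfWindow half-window around each blink, seconds (default 0.2).
#' @param minDurS minimum suprathreshold duration, seconds (default 0.02):
#'   blinks are sustained 100-300 ms excursions, so single-sample noise
#'   crossings of the z threshold are not treated as blinks.
#' @param nComponents number of projected components (default 1).
#' @return the cleaned recording; \code{meta$blinkWindows} holds the detected
#'   windows, \code{meta$ssp} the projector. If no blink is found the
#'   recording is returned unchanged with a warning.
#' @export
blinkProject <- function(recording, zThresh = 3, halfWindow = 0.2,
                         minDurS = 0.02, nComponents = 1L) {
  fpz <- match("Fpz", recording@channels)
  stopIfNot(!is.na(fpz), "blink projection needs an Fpz channel")
  x <- recording@data
  sfreq <- recording@sfreq
  ref <- x[fpz, ]
  base <- if (length(recording@blinkPeriod) == 2) {
    i <- round(recording@blinkPeriod * sfreq)
    ref[max(1, i[1] + 1):min(length(ref), max(i[2], i[1] + sfreq))]
  } else ref
  z <- (ref - stats::median(base)) / max(stats::mad(base), 1e-9)
  hot <- abs(z) > zThresh
  runs <- boolRuns(hot)
  runs <- runs[runs$length >= max(1L, round(minDurS * sfreq)), , drop = FALSE]
  if (!nrow(runs)) {
    warning("no blinks detected; recording returned unchanged", call. = FALSE)
    return(recording)
  }
  half <- round(halfWindow * sfreq)
  win <- cbind(pmax(1L, runs$start - half),
               pmin(ncol(x), runs$start + runs$length - 1L + half))
  # merge overlapping windows
  ord <- order(win[, 1])
  win <- win[ord, , drop = FALSE]
  merged <- win[1, , drop = FALSE]
  for (r in seq_len(nrow(win))[-1]) {
    if (win[r, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], win[r, 2])
    else merged <- rbind(merged, win[r, ])
  }
  idx <- unlist(apply(merged, 1, function(w) w[1]:w[2], simplify = FALSE))
  seg <- x[, idx, drop = FALSE]
  seg <- seg - rowMeans(seg)
  sv <- svd(seg, nu = nComponents, nv = 0)
  U <- sv$u
  recording@data <- x - U %*% (t(U) %*% x)
  recording@meta$blinkWindows <- data.frame(start = (merged[, 1] - 1) / sfreq,
                                            end = merged[, 2] / sfreq)
  recording@meta$ssp <- U
  recording
}

# Task-specific epoching windows (seconds relative to the event onset).
epochPlan <- function(task, mode) {
  if (task == "oddball" && mode == "bci")
    return(list(windows = list(target = c(0, 0.7), nontarget = c(0, 0.7)),
                baseline = c(0, 0.1)))
  switch(task,
    eyes = list(windows = list(open = c(0.5, 5), closed = c(0.5, 5)),
                baseline = NULL),
    motor = list(windows = list(move = c(0, 4), rest = c(2, 6)),
                 baseline = NULL),
    ssvep = list(windows = list(ssvep_5 = "overlap3", ssvep_6 = "overlap3",
                                rest = c(0, 5)),
                 baseline = NULL),
    oddball = list(windows = list(target = c(-0.2, 0.7),
                                  nontarget = c(-0.2, 0.7)),
                   baseline = c(-0.2, 0)),
    stop("unknown task '", task, "'", call. = FALSE))
}

#' Extract task epochs from a recording
#'
#' Task-specific windows: eyes open/closed \code{[0.5, 5]} s; motor
#' \code{[0, 4]} s for clutching and \code{[2, 6]} s of the rest period;
#' SSVEP three 50%-overlapping 5 s epochs per 10 s trial; oddball
#' \code{[-0.2, 0.7]} s baseline-corrected on \code{[-0.2, 0]} s. In BCI
#' mode the oddball window is \code{[0, 0.7]} s baseline-corrected against
#' the first 100 ms. Markers whose window falls outside the recording are
#' skipped with a warning.
#'
#' @param recording a [Recording-class] with events.
#' @param task one of "eyes", "motor", "ssvep", "oddball" (defaults to the
#'   recording's own task).
#' @param mode "validation" or "bci".
#' @param window optional (start, end) seconds overriding the task windows
#'   for every selected label (e.g. \code{c(-6, 4)} around movement onsets
#'   for time-frequency maps whose baseline precedes the event).
#' @param labels optional label subset when \code{window} is given.
#' @return an [EpochSet-class]; the per-epoch transport-loss mask is carried
#'   along for the loss rejection rule.
#' @export
extractEpochs <- function(recording, task = recording@meta$task,
                          mode = c("validation", "bci"), window = NULL,
                          labels = NULL) {
  mode <- match.arg(mode)
  stopIfNot(nrow(recording@events) > 0, "recording has no event markers")
  plan <- epochPlan(task, mode)
  if (!is.null(window)) {
    sel <- labels %||% names(plan$windows)
    plan$windows <- stats::setNames(rep(list(window), length(sel)), sel)
    plan$baseline <- NULL
  }
  sfreq <- recording@sfreq
  n <- ncol(recording@data)
  slices <- list()
  labels <- character()
  for (k in seq_len(nrow(recording@events))) {
    lab <- recording@events$label[k]
    w <- plan$windows[[lab]]
    if (is.null(w)) next
    subWins <- if (identical(w, "overlap3"))
      list(c(0, 5), c(2.5, 7.5), c(5, 10)) else list(w)
    for (sw in subWins) {
      i0 <- round((recording@events$onset[k] + sw[1]) * sfreq) + 1L
      len <- round((sw[2] - sw[1]) * sfreq)
      if (i0 < 1 || i0 + len - 1L > n) {
        warning("marker at ", recording@events$onset[k],
                " s falls outside the recording; epoch skipped", call. = FALSE)
        next
      }
      slices[[length(slices) + 1L]] <- c(i0, len)
      labels <- c(labels, lab)
    }
  }
  stopIfNot(length(slices) > 0, "no epochs could be extracted")
  len <- slices[[1]][2]
  firstLab <- labels[1]
  w1 <- plan$windows[[firstLab]]
  tRel0 <- if (identical(w1, "overlap3")) 0 else w1[1]
  times <- tRel0 + seq(0, by = 1 / sfreq, length.out = len)
  nTr <- length(slices)
  nch <- nrow(recording@data)
  dat <- array(0, c(nTr, nch, len))
  lm <- matrix(FALSE, nTr, len)
  for (tr in seq_len(nTr)) {
    i0 <- slices[[tr]][1]
    idx <- i0:(i0 + len - 1L)
    dat[tr, , ] <- recording@data[, idx]
    lm[tr, ] <- recording@lostMask[idx]
  }
  if (!is.null(plan$baseline)) {
    bidx <- which(times >= plan$baseline[1] & times <= plan$baseline[2])
    # subtract the per-trial, per-channel baseline mean
    bl <- apply(dat[, , bidx, drop = FALSE], c(1, 2), mean)
    dat <- dat - array(rep(bl, len), c(nTr, nch, len))
  }
  newEpochSet(dat, times, recording@channels, sfreq, labels, lm,
              meta = list(task = task, mode = mode,
                          profile = recording@meta$profile))
}

#' Apply the multi-rule epoch rejection
#'
#' Four rules, in order, each recording the first one it triggers:
#' \describe{
#'   \item{loss}{more than \code{lossLimit} (default 20, strictly) consecutive
#'     samples lost in the epoch;}
#'   \item{amplitude}{any sample outside \code{+/- ampLimitUv} (50 uV in
#'     validation mode, 100 uV in BCI mode);}
#'   \item{psd}{band-mean multitaper PSD over 20-30 Hz above
#'     \code{psdLimitDb} (dB re 1 uV^2/Hz) on any channel (validation mode
#'     only); the band mean is robust to single-bin spikes;}
#'   \item{linear}{per-channel linear fit of amplitude on time with r^2 above
#'     \code{r2Limit} (constant channels define r^2 = 0; validation only).}
#' }
#' BCI mode applies only the loss and amplitude rules. Per-rule counts are
#' reported in \code{meta$rejectionCounts}.
#'
#' @param epochs an [EpochSet-class].
#' @param mode "validation" or "bci".
#' @param lossLimit,ampLimitUv,psdLimitDb,r2Limit rule thresholds; the
#'   defaults are the pipeline presets.
#' @return the epochs with \code{rejected}/\code{rejectReason} filled.
#' @export
rejectEpochs <- function(epochs, mode = c("validation", "bci"),
                         lossLimit = 20L, ampLimitUv = NULL,
                         psdLimitDb = 60, r2Limit = 0.85) {
  mode <- match.arg(mode)
  if (is.null(ampLimitUv)) ampLimitUv <- if (mode == "validation") 50 else 100
  nTr <- nTrials(epochs)
  reason <- rep(NA_character_, nTr)
  tvec <- epochs@times
  for (tr in seq_len(nTr)) {
    runs <- boolRuns(epochs@lostMask[tr, ])
    if (nrow(runs) && max(runs$length) > lossLimit) {
      reason[tr] <- "loss"
      next
    }
    x <- epochs@data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (max(abs(x)) > ampLimitUv) {
      reason[tr] <- "amplitude"
      next
    }
    if (mode == "validation") {
      hit <- FALSE
      for (ch in seq_len(nrow(x))) {
        ps <- multitaperPsd(x[ch, ], epochs@sfreq, fmin = 20, fmax = 30)
        if (10 * log10(max(mean(ps$psd), 1e-300)) > psdLimitDb) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        reason[tr] <- "psd"
        next
      }
      for (ch in seq_len(nrow(x))) {
        y <- x[ch, ]
        vy <- stats::var(y)
        if (vy < 1e-20) next  # constant channel: r^2 defined as 0
        r2 <- stats::cor(y, tvec)^2
        if (!is.na(r2) && r2 > r2Limit) {
          reason[tr] <- "linear"
          break
        }
      }
    }
  }
  epochs@rejected <- !is.na(reason)
  epochs@rejectReason <- reason
  counts <- table(factor(reason, levels = c("loss", "amplitude", "psd",
                                            "linear", "manual")))
  epochs@meta$rejectionCounts <- as.list(counts)
  epochs
}

#' Dry-run rejection report
#'
#' The manual-validation step of the semi-automatic procedure is replaced by
#' a report listing every flagged epoch with its triggering rule, for visual
#' inspection offline.
#'
#' @param epochs a rejected [EpochSet-class].
#' @return data.frame with columns trial, label, reason.
#' @export
rejectionReport <- function(epochs) {
  flagged <- which(epochs@rejected)
  data.frame(trial = flagged, label = epochs@labels[flagged],
             reason = epochs@rejectReason[flagged])
}
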