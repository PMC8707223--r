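# Spectral estimation: Welch, multitaper (DPSS), Morlet ERSP.

# Cache DPSS tapers across calls: computing them is the expensive part.
.dpssCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Tapers are the leading eigenvectors of the symmetric tridiagonal
#' concentration matrix. For long windows (n > 1200) they are computed at
#' n = 1024, interpolated to n, and re-orthonormalized; the spectral
#' concentration loss of this classic shortcut is negligible for PSD
#' averaging. Results are cached.
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (default \code{max(1, floor(2 * nw - 1))}).
#' @return n x k matrix; columns have unit energy.
#' @export
dpssTapers <- function(n, nw, k = max(1L, floor(2 * nw - 1))) {
  key <- sprintf("%d-%.6g-%d", n, nw, k)
  hit <- .dpssCache[[key]]
  if (!is.null(hit)) return(hit)
  base <- if (n > 1200) 1024L else n
  w <- nw / n
  i <- seq_len(base) - 1
  dg <- ((base - 1 - 2 * i) / 2)^2 * cos(2 * pi * w * n / base)
  od <- i[-1] * (base - i[-1]) / 2
  m <- diag(dg)
  m[cbind(seq_len(base - 1), seq_len(base - 1) + 1)] <- od
  m[cbind(seq_len(base - 1) + 1, seq_len(base - 1))] <- od
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  if (base != n) {
    tap <- apply(tap, 2, function(v)
      stats::spline(seq(0, 1, length.out = base), v,
                    xout = seq(0, 1, length.out = n))$y)
    tap <- qr.Q(qr(tap))
  }
  # sign convention: symmetric tapers positive mean, others positive slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  .dpssCache[[key]] <- tap
  tap
}

#' Multitaper PSD of a single signal
#'
#' Non-adaptive (equal-weight) multitaper estimate with half-bandwidth
#' \code{halfBandwidth} Hz: \code{nw = n / sfreq * halfBandwidth},
#' \code{k = 2 nw - 1} tapers. Units uV^2/Hz (one-sided);
#' \code{dB = 10 log10(PSD / 1 uV^2/Hz)}.
#'
#' @param x numeric signal (uV).
#' @param sfreq sampling rate, Hz.
#' @param halfBandwidth Hz (default 2).
#' @param fmin,fmax returned frequency range, Hz.
#' @return list with \code{freq} and \code{psd}.
#' @export
multitaperPsd <- function(x, sfreq, halfBandwidth = 2, fmin = 1, fmax = 30) {
  n <- length(x)
  nw <- max(1, n / sfreq * halfBandwidth)
  tap <- dpssTapers(n, nw)
  x <- x - mean(x)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (j in seq_len(ncol(tap))) {
    sp <- stats::fft(x * tap[, j])[seq_len(nf)]
    acc <- acc + Mod(sp)^2
  }
  psd <- acc / ncol(tap) / sfreq
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  freq <- (seq_len(nf) - 1) * sfreq / n
  keep <- freq >= fmin & freq <= fmax
  list(freq = freq[keep], psd = psd[keep])
}

#' Welch PSD of a single signal
#'
#' Hanning window, 2000-sample segments, 1000-sample overlap, 5000-point FFT
#' by default (frequency step 0.1 Hz at 500 Hz). Segments are mean-detrended;
#' one-sided density in uV^2/Hz.
#'
#' @param x numeric signal (uV).
#' @param sfreq sampling rate, Hz.
#' @param segment segment length, samples.
#' @param overlap overlap between consecutive segments, samples.
#' @param nfft FFT length (zero-padded).
#' @return list with \code{freq} and \code{psd}.
#' @export
welchPsd <- function(x, sfreq, segment = 2000L, overlap = 1000L,
                     nfft = 5000L) {
  n <- length(x)
  stopIfNot(n >= segment,
            "signal (%d samples) shorter than the Welch segment (%d)",
            n, segment)
  step <- segment - overlap
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- hannWindow(segment)
  scale <- 1 / (sfreq * sum(w^2))
  nf <- floor(nfft / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(c(seg, numeric(nfft - segment)))[seq_len(nf)]
    acc <- acc + Mod(sp)^2 * scale
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * sfreq / nfft, psd = psd)
}

#' Per-epoch PSD features
#'
#' @param epochs an [EpochSet-class].
#' @param method "multitaper" (1-30 Hz, half-bandwidth 2 Hz, non-adaptive)
#'   or "welch" (Hanning, 2000-sample segments, 1000 overlap, 5000-point
#'   FFT). Welch errors, naming the epoch, when an epoch is shorter than the
#'   segment.
#' @param channels channel names to include (default all).
#' @param fmin,fmax frequency range, Hz.
#' @return list with \code{freq} and \code{psd}, an array
#'   trials x channels x frequencies (uV^2/Hz).
#' @export
psdFeatures <- function(epochs, method = c("multitaper", "welch"),
                        channels = channelNames(epochs), fmin = 1, fmax = 30) {
  method <- match.arg(method)
  chIdx <- match(channels, epochs@channels)
  stopIfNot(!anyNA(chIdx), "unknown channel(s): %s",
            paste(channels[is.na(chIdx)], collapse = ", "))
  nTr <- nTrials(epochs)
  nt <- dim(epochs@data)[3]
  if (method == "welch" && nt < 2000)
    stop("epoch 1 (", nt, " samples) is shorter than the 2000-sample ",
         "Welch segment", call. = FALSE)
  one <- function(v) {
    if (method == "multitaper")
      multitaperPsd(v, epochs@sfreq, fmin = fmin, fmax = fmax)
    else {
      ps <- welchPsd(v, epochs@sfreq)
      keep <- ps$freq >= fmin & ps$freq <= fmax
      list(freq = ps$freq[keep], psd = ps$psd[keep])
    }
  }
  probe <- one(epochs@data[1, chIdx[1], ])
  out <- array(0, c(nTr, length(chIdx), length(probe$freq)))
  for (tr in seq_len(nTr)) for (c2 in seq_along(chIdx))
    out[tr, c2, ] <- one(epochs@data[tr, chIdx[c2], ])$psd
  dimnames(out) <- list(NULL, channels, NULL)
  list(freq = probe$freq, psd = out)
}

#' Morlet event-related spectral perturbation
#'
#' Time-frequency decomposition with complex Morlet wavelets at linearly
#' increasing frequencies 1..30 Hz whose cycle counts also increase linearly
#' 1..30 (matched index-wise). Power is averaged over trials, then converted
#' to dB against the mean power of the pre-event baseline window per
#' frequency and channel.
#'
#' @param epochs an [EpochSet-class] whose time axis contains the baseline.
#' @param baselineWindow (start, end) seconds (default c(-6, 0)).
#' @param freqs wavelet frequencies, Hz.
#' @param cycles wavelet cycles, matched to \code{freqs}.
#' @param channels channels to decompose (default all).
#' @return list with \code{times}, \code{freqs}, \code{db} (channels x
#'   freqs x time) and \code{power} (same shape, uV^2).
#' @export
erspMorlet <- function(epochs, baselineWindow = c(-6, 0), freqs = 1:30,
                       cycles = 1:30, channels = channelNames(epochs)) {
  tvec <- epochs@times
  if (baselineWindow[1] < min(tvec) - 1e-9 ||
      baselineWindow[2] > max(tvec) + 1e-9)
    stop("baseline window [", baselineWindow[1], ", ", baselineWindow[2],
         "] s lies outside the epoch", call. = FALSE)
  stopIfNot(length(freqs) == length(cycles),
            "freqs and cycles must be matched index-wise")
  chIdx <- match(channels, epochs@channels)
  sfreq <- epochs@sfreq
  nTr <- nTrials(epochs)
  nt <- length(tvec)
  pow <- array(0, c(length(chIdx), length(freqs), nt))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- cycles[fi] / (2 * pi * f)
    half <- ceiling(3.5 * sigma * sfreq)
    kt <- (-half:half) / sfreq
    kern <- exp(2i * pi * f * kt) * exp(-kt^2 / (2 * sigma^2))
    kern <- kern / sqrt(sum(Mod(kern)^2))
    L <- length(kern)
    nfft <- 2^ceiling(log2(nt + L - 1))
    kf <- stats::fft(c(kern, complex(real = numeric(nfft - L))))
    ctr <- half + 1L
    for (ci in seq_along(chIdx)) {
      acc <- numeric(nt)
      for (tr in seq_len(nTr)) {
        x <- epochs@data[tr, chIdx[ci], ]
        xf <- stats::fft(c(x, numeric(nfft - nt)))
        conv <- stats::fft(xf * kf, inverse = TRUE) / nfft
        acc <- acc + Mod(conv[ctr:(ctr + nt - 1L)])^2
      }
      pow[ci, fi, ] <- acc / nTr
    }
  }
  bidx <- which(tvec >= baselineWindow[1] & tvec <= baselineWindow[2])
  db <- pow
  for (ci in seq_along(chIdx)) for (fi in seq_along(freqs)) {
    base <- mean(pow[ci, fi, bidx])
    db[ci, fi, ] <- 10 * log10(pow[ci, fi, ] / max(base, 1e-300))
  }
  dimnames(db) <- dimnames(pow) <- list(channels, NULL, NULL)
  list(times = tvec, freqs = freqs, db = db, power = pow)
}
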