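#' Per-condition average waveform
#'
#' Grand-average over accepted trials per condition, with per-bin sd and,
#' when a query window is given, the peak amplitude and latency of the mean
#' waveform inside it.
#'
#' @param epochs an [EpochSet-class] (rejected trials are excluded).
#' @param channel channel to summarize peaks on (default "Cz").
#' @param peakWindow optional (start, end) seconds for the peak query.
#' @return list with one element per condition: \code{mean} (channels x
#'   time), \code{sd}, \code{n}, and optionally \code{peak} (amplitude uV,
#'   latency s).
#' @export
erpAverage <- function(epochs, channel = "Cz", peakWindow = NULL) {
  keep <- !epochs@rejected
  labs <- unique(epochs@labels)
  out <- list()
  for (lab in labs) {
    idx <- which(keep & epochs@labels == lab)
    if (!length(idx))
      stop("condition '", lab, "' has no accepted trials", call. = FALSE)
    d <- epochs@data[idx, , , drop = FALSE]
    m <- apply(d, c(2, 3), mean)
    s <- apply(d, c(2, 3), stats::sd)
    rownames(m) <- rownames(s) <- epochs@channels
    el <- list(mean = m, sd = s, n = length(idx))
    if (!is.null(peakWindow)) {
      ci <- match(channel, epochs@channels)
      widx <- which(epochs@times >= peakWindow[1] &
                    epochs@times <= peakWindow[2])
      pk <- widx[which.max(m[ci, widx])]
      el$peak <- c(amplitude = m[ci, pk], latency = epochs@times[pk])
    }
    out[[lab]] <- el
  }
  out
}

clusterMasses <- function(tvals, tcrit) {
  # clusters of same-sign suprathreshold bins; mass = sum of t
  out <- numeric()
  for (sgn in c(1, -1)) {
    hot <- sgn * tvals > tcrit
    runs <- boolRuns(hot)
    if (nrow(runs))
      out <- c(out, vapply(seq_len(nrow(runs)), function(r)
        sum(tvals[runs$start[r]:(runs$start[r] + runs$length[r] - 1L)]),
        numeric(1)))
  }
  out
}

#' Compare two conditions bin-by-bin
#'
#' \code{correction = "bonferroni"}: two-sided Welch t-test per bin at
#' \code{alpha / m}. \code{correction = "cluster"}: dependent-sample t per
#' bin on the paired differences, clusters formed where |t| exceeds the
#' two-sided alpha t-quantile, cluster mass = sum of t within the cluster,
#' null distribution from sign-flip permutations of the paired differences
#' (exhaustive when \code{2^n <= nPerm}, otherwise \code{nPerm} random
#' flips); corrected p = proportion of permutation max-|mass| values >= the
#' observed |mass|.
#'
#' @param a,b trials x bins matrices on the same bin grid. Cluster mode
#'   requires equal trial counts (paired trials).
#' @param correction "bonferroni" or "cluster".
#' @param alpha significance level (default 0.05).
#' @param nPerm permutation count for cluster correction (default 1000).
#' @param seed integer seed for the random flips.
#' @return For bonferroni: data.frame(bin, t, p, significant). For cluster:
#'   list with \code{t} (per bin), \code{clusters} (data.frame start, end,
#'   mass, p), and \code{significant} (logical per bin).
#' @export
compareConditions <- function(a, b, correction = c("bonferroni", "cluster"),
                              alpha = 0.05, nPerm = 1000L, seed = 1L) {
  correction <- match.arg(correction)
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopIfNot(ncol(a) == ncol(b), "bin grids must match")
  stopIfNot(nrow(a) >= 2 && nrow(b) >= 2,
            "need at least 2 trials per condition")
  m <- ncol(a)
  if (correction == "bonferroni") {
    tt <- vapply(seq_len(m), function(j) {
      ht <- stats::t.test(a[, j], b[, j])
      c(ht$statistic, ht$p.value)
    }, numeric(2))
    return(data.frame(bin = seq_len(m), t = tt[1, ], p = tt[2, ],
                      significant = tt[2, ] < alpha / m))
  }
  stopIfNot(nrow(a) == nrow(b), "cluster correction requires paired trials")
  d <- a - b
  n <- nrow(d)
  tcrit <- stats::qt(1 - alpha / 2, n - 1)
  ss <- colSums(d^2)
  tOf <- function(mn) {
    v <- (ss - n * mn^2) / (n - 1)
    mn / sqrt(pmax(v, 1e-300) / n)
  }
  tobs <- tOf(colMeans(d))
  obsMass <- clusterMasses(tobs, tcrit)
  exhaustive <- 2^n <= nPerm
  signs <- if (exhaustive) {
    s <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    t(s)
  } else withSeed(seed, {
    matrix(sample(c(1, -1), n * nPerm, replace = TRUE), nrow = n)
  })
  P <- ncol(signs)
  permMeans <- crossprod(signs, d) / n  # P x m
  maxMass <- vapply(seq_len(P), function(p) {
    masses <- clusterMasses(tOf(permMeans[p, ]), tcrit)
    if (length(masses)) max(abs(masses)) else 0
  }, numeric(1))
  clusters <- data.frame(start = integer(), end = integer(),
                         mass = numeric(), p = numeric())
  sig <- rep(FALSE, m)
  for (sgn in c(1, -1)) {
    runs <- boolRuns(sgn * tobs > tcrit)
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1L)
      mass <- sum(tobs[idx])
      p <- if (exhaustive) mean(maxMass >= abs(mass))
        else (1 + sum(maxMass >= abs(mass))) / (P + 1)
      clusters <- rbind(clusters,
                        data.frame(start = idx[1], end = idx[length(idx)],
                                   mass = mass, p = p))
      if (p < alpha) sig[idx] <- TRUE
    }
  }
  list(t = tobs, clusters = clusters, significant = sig,
       nPerm = P, exhaustive = exhaustive)
}

#' Trial-subsampling power curve
#'
#' For each trial count n in \code{nGrid}: draw n trials per condition
#' without replacement, test the per-trial scalar features with a two-sided
#' t-test at \code{alpha}, repeat \code{nPerm} times, and record the
#' proportion of significant draws. \code{n80} is the smallest n whose
#' proportion reaches \code{target}.
#'
#' @param featA,featB numeric vectors of per-trial scalar features (one per
#'   accepted trial), or matrices whose rows are trials combined with
#'   \code{featureFn}.
#' @param nGrid trial counts to evaluate; entries above the available trial
#'   count are dropped with a warning.
#' @param featureFn optional function mapping a trial row to a scalar.
#' @param nPerm subsampling permutations per n (default 1000).
#' @param alpha significance level (default 0.05).
#' @param target power target (default 0.8).
#' @param seed integer seed.
#' @return a [PowerCurve-class].
#' @export
powerCurve <- function(featA, featB, nGrid, featureFn = NULL,
                       nPerm = 1000L, alpha = 0.05, target = 0.8,
                       seed = 1L) {
  if (!is.null(featureFn)) {
    featA <- apply(as.matrix(featA), 1, featureFn)
    featB <- apply(as.matrix(featB), 1, featureFn)
  }
  featA <- as.numeric(featA)
  featB <- as.numeric(featB)
  avail <- min(length(featA), length(featB))
  nGrid <- sort(unique(as.integer(nGrid)))
  if (any(nGrid > avail)) {
    warning("trial counts above the available ", avail,
            " trials dropped from the grid", call. = FALSE)
    nGrid <- nGrid[nGrid <= avail]
  }
  stopIfNot(length(nGrid) > 0 && min(nGrid) >= 2,
            "need a grid of trial counts >= 2")
  prop <- withSeed(seed, {
    vapply(nGrid, function(n) {
      hits <- 0L
      for (p in seq_len(nPerm)) {
        xa <- featA[sample.int(length(featA), n)]
        xb <- featB[sample.int(length(featB), n)]
        pv <- tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) 1)
        if (!is.na(pv) && pv < alpha) hits <- hits + 1L
      }
      hits / nPerm
    }, numeric(1))
  })
  reach <- which(prop >= target)
  new("PowerCurve", nGrid = nGrid, proportion = prop,
      n80 = if (length(reach)) as.numeric(nGrid[reach[1]]) else NA_real_,
      nPerm = as.integer(nPerm), alpha = alpha, target = target)
}

#' Per-trial scalar features for the power analysis
#'
#' \code{trialPsdPeak}: per accepted trial, the peak of the PSD at one
#' channel inside a frequency band (the features used for the eyes, motor
#' and SSVEP tasks). \code{trialErpPeak}: per accepted trial, the maximum
#' amplitude at one channel inside a time window (the P300 feature).
#'
#' @param epochs an [EpochSet-class].
#' @param label condition label to select trials from.
#' @param channel channel name.
#' @param band (low, high) Hz for the PSD peak.
#' @param method PSD estimator (see [psdFeatures()]).
#' @param window (start, end) seconds for the ERP peak.
#' @return numeric vector, one scalar per accepted trial.
#' @export
trialPsdPeak <- function(epochs, label, channel, band = c(8, 12),
                         method = "welch") {
  acc <- acceptedTrials(epochs)
  idx <- which(trialLabels(acc) == label)
  stopIfNot(length(idx) > 0, "no accepted trials labelled '%s'", label)
  sub <- acc@data[idx, match(channel, acc@channels), , drop = FALSE]
  vapply(seq_along(idx), function(i) {
    v <- sub[i, 1, ]
    ps <- if (method == "welch") welchPsd(v, acc@sfreq)
      else multitaperPsd(v, acc@sfreq, fmin = band[1], fmax = band[2])
    keep <- ps$freq >= band[1] & ps$freq <= band[2]
    max(ps$psd[keep])
  }, numeric(1))
}

#' @rdname trialPsdPeak
#' @export
trialErpPeak <- function(epochs, label, channel = "Cz",
                         window = c(0.25, 0.55)) {
  acc <- acceptedTrials(epochs)
  idx <- which(trialLabels(acc) == label)
  stopIfNot(length(idx) > 0, "no accepted trials labelled '%s'", label)
  widx <- which(acc@times >= window[1] & acc@times <= window[2])
  vapply(idx, function(i) max(acc@data[i, match(channel, acc@channels), widx]),
         numeric(1))
}
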