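# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stage tag, staying within 32-bit
# integer range so set.seed() is portable.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Constructor bypassing initialize() boilerplate; validity still checked.
newEpochSet <- function(data, times, channels, sfreq, labels, lostMask,
                        rejected = rep(FALSE, dim(data)[1]),
                        rejectReason = rep(NA_character_, dim(data)[1]),
                        meta = list()) {
  new("EpochSet", data = data, times = times, channels = channels,
      sfreq = sfreq, labels = labels, lostMask = lostMask,
      rejected = rejected, rejectReason = rejectReason, meta = meta)
}

# Moving RMS with a centred rectangular window of `width` samples.
movingRms <- function(x, width) {
  x2 <- x^2
  cs <- cumsum(c(0, x2))
  n <- length(x)
  half <- floor(width / 2)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# Maximal runs of TRUE in a logical vector: data.frame(start, length).
boolRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Hann window matching the classic 'hanning' definition used by FFT toolkits.
hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

formatOffsetMatrix <- function(object) {
  k <- length(object@devices)
  out <- matrix("", k, k, dimnames = list(object@devices, object@devices))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (i == j) "0 +/- 0"
    else sprintf("%.0f +/- %.0f [%d]", object@meanMs[i, j], object@sdMs[i, j],
                 abs(object@samples[i, j]))
  }
  out
}

stopIfNot <- function(cond, msg, ...) if (!cond) stop(sprintf(msg, ...), call. = FALSE)
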