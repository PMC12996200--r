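#' Preprocessing configuration
#'
#' @param target_rate_hz sampling rate the series is resampled to.
#' @param band_hz length-2 numeric `(low, high)` pass band in Hz; `low = 0`
#'   disables the high-pass side, `high >= target_rate_hz/2` the low-pass side.
#' @param detrend remove a linear trend before filtering.
#' @param normalize `"unit_rms"`, `"zscore"` or `"none"`; applied last.
#' @param transition_hz width of the raised-cosine filter transition band.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate_hz = 2000, band_hz = c(25, 900),
                              detrend = TRUE,
                              normalize = c("unit_rms", "zscore", "none"),
                              transition_hz = 10) {
  normalize <- match.arg(normalize)
  assert_scalar_num(target_rate_hz, "target_rate_hz")
  if (length(band_hz) != 2 || band_hz[1] < 0 || band_hz[1] >= band_hz[2]) {
    stop("band_hz must satisfy 0 <= low < high")
  }
  if (band_hz[1] > 0 && band_hz[2] >= target_rate_hz / 2) {
    # a high band edge at/above Nyquist simply disables the low-pass side
    band_hz[2] <- target_rate_hz / 2
  }
  if (band_hz[1] >= target_rate_hz / 2) {
    stop("band low edge is above the Nyquist of target_rate_hz")
  }
  structure(list(target_rate_hz = target_rate_hz, band_hz = band_hz,
                 detrend = isTRUE(detrend), normalize = normalize,
                 transition_hz = transition_hz),
            class = "preprocess_config")
}

#' Standardize a recording into an analysis-ready series
#'
#' Resamples to the target rate, optionally removes a linear trend, applies a
#' zero-phase spectral band-pass filter, and normalizes. The filter has unit
#' gain across the pass band (so repeated application is idempotent) and a
#' raised-cosine transition of width `transition_hz` below the low edge and
#' above the high edge; content beyond the transition is removed outright.
#'
#' @param recording a `pcg_recording` (see [read_wav()], [synthesize_pcg()]).
#' @param cfg a [preprocess_config()].
#' @return Numeric vector of length `round(duration * target_rate_hz)`.
#' @export
preprocess <- function(recording, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  x <- as.numeric(recording$samples)
  rate <- recording$rate_hz
  if (cfg$band_hz[1] >= cfg$target_rate_hz / 2) {
    stop("band low edge is above the Nyquist of the target rate")
  }
  x <- resample_series(x, rate, cfg$target_rate_hz)
  if (cfg$detrend) x <- detrend_linear(x)
  x <- fft_bandpass(x, cfg$target_rate_hz, cfg$band_hz[1], cfg$band_hz[2],
                    cfg$transition_hz)
  switch(cfg$normalize,
    none = x,
    zscore = {
      s <- sd(x)
      if (s == 0) stop("cannot z-score a constant series")
      (x - mean(x)) / s
    },
    unit_rms = {
      r <- sqrt(mean(x^2))
      if (r == 0) stop("cannot rms-normalize an all-zero series")
      x / r
    }
  )
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * sum(t * x) / sum(t * t)
}

# Zero-phase spectral band-pass: mirror-pad, FFT, multiply by a real
# frequency response that is exactly 1 in [low, high] and rolls off with a
# raised cosine over `trans` Hz, inverse FFT, unpad. Exact passband unity
# makes repeated application idempotent up to roundoff.
fft_bandpass <- function(x, rate, low, high, trans = 10) {
  n <- length(x)
  nyq <- rate / 2
  do_hp <- low > 0
  do_lp <- high < nyq - 1e-9
  if (!do_hp && !do_lp) return(x)
  p <- min(n, max(16L, as.integer(round(rate))))
  xp <- c(rev(x[1:p]), x, rev(x[(n - p + 1):n]))
  N <- length(xp)
  f <- (0:(N - 1)) * rate / N
  f <- pmin(f, rate - f)  # two-sided -> absolute frequency
  H <- rep(1, N)
  if (do_hp) {
    t0 <- max(low - trans, 0)
    ramp <- (f - t0) / max(low - t0, .Machine$double.eps)
    H <- H * ifelse(f <= t0, 0, ifelse(f >= low, 1,
                    0.5 - 0.5 * cos(pi * ramp)))
  }
  if (do_lp) {
    t1 <- min(high + trans, nyq)
    ramp <- (f - high) / max(t1 - high, .Machine$double.eps)
    H <- H * ifelse(f >= t1, 0, ifelse(f <= high, 1,
                    0.5 + 0.5 * cos(pi * ramp)))
  }
  y <- Re(fft(fft(xp) * H, inverse = TRUE)) / N
  y[(p + 1):(p + n)]
}

# Resample to a new rate via polyphase filtering (signal::resample) using a
# small-denominator rational approximation of the rate ratio; output is
# trimmed/padded to the exact expected length.
resample_series <- function(x, from, to) {
  if (isTRUE(all.equal(from, to))) return(x)
  target_len <- round(length(x) * to / from)
  pq <- rational_approx(to / from, 8192)
  y <- signal::resample(x, pq[1], pq[2])
  if (length(y) >= target_len) {
    y[seq_len(target_len)]
  } else {
    c(y, rep(y[length(y)], target_len - length(y)))
  }
}

rational_approx <- function(r, max_den) {
  # continued-fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  z <- r
  repeat {
    a <- floor(z)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    frac <- z - a
    if (frac < 1e-12) break
    z <- 1 / frac
  }
  c(as.integer(p1), as.integer(q1))
}
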