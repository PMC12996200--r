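#' Welch power spectral density
#'
#' Averaged Hann-windowed periodograms. One-sided density in amplitude^2/Hz;
#' the integral over frequency recovers the signal's mean power (Parseval,
#' up to window-correction tolerance).
#'
#' @param x numeric series.
#' @param rate_hz sampling rate.
#' @param seg_len segment length in samples (default 1 second).
#' @param overlap_frac overlap between segments in `[0, 1)`.
#' @return A `pcg_spectrum`: list with ascending `freqs_hz` (from 0) and
#'   nonnegative `power`.
#' @export
power_spectrum <- function(x, rate_hz, seg_len = NULL, overlap_frac = 0.5) {
  x <- as.numeric(x)
  seg_len <- as.integer(seg_len %||% min(length(x), round(rate_hz)))
  if (seg_len > length(x)) stop("series shorter than one segment")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  hop <- max(1L, as.integer(round(seg_len * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  U <- sum(w^2)
  nfreq <- seg_len %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    X <- fft(x[s:(s + seg_len - 1L)] * w)
    acc <- acc + Mod(X[1:nfreq])^2
  }
  P <- acc / (length(starts) * rate_hz * U)
  scale <- rep(2, nfreq)
  scale[1] <- 1
  if (seg_len %% 2 == 0) scale[nfreq] <- 1
  structure(list(freqs_hz = (0:(nfreq - 1)) * rate_hz / seg_len,
                 power = P * scale),
            class = "pcg_spectrum")
}

#' Band powers from a spectrum
#'
#' Integrates the power density over contiguous bands `[e_i, e_{i+1})` (the
#' last band includes its upper edge), and reports `log10` with a small
#' floor so silent bands stay finite.
#'
#' @param spectrum a `pcg_spectrum`.
#' @param band_edges_hz ascending band edges within Nyquist.
#' @param floor_eps floor added inside the log.
#' @return data.frame with `band_low`, `band_high`, `power`, `log10_power`.
#' @export
band_powers <- function(spectrum, band_edges_hz, floor_eps = 1e-12) {
  e <- band_edges_hz
  if (is.unsorted(e, strictly = TRUE)) stop("band edges must be strictly ascending")
  if (length(e) < 2) stop("need at least one band")
  f <- spectrum$freqs_hz
  df <- if (length(f) > 1) f[2] - f[1] else 1
  nb <- length(e) - 1
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- f >= e[b] & (if (b == nb) f <= e[b + 1] else f < e[b + 1])
    if (!any(sel)) stop(sprintf("empty band [%g, %g): no spectral bins", e[b], e[b + 1]))
    out[b] <- sum(spectrum$power[sel]) * df
  }
  data.frame(band_low = e[-length(e)], band_high = e[-1], power = out,
             log10_power = log10(out + floor_eps))
}

#' Real cepstrum
#'
#' Inverse transform of the log magnitude spectrum (floored at `floor_eps`
#' to avoid minus infinity); returns the first `n_coeff` quefrency
#' coefficients. Periodic spectral structure — e.g. an echo at delay `d`
#' samples — appears as a peak at quefrency `d`.
#'
#' @param x numeric series with `length(x) >= 2 * n_coeff`.
#' @param rate_hz sampling rate (quefrency spacing is `1/rate_hz` seconds).
#' @param n_coeff number of coefficients returned.
#' @param floor_eps magnitude floor before the log.
#' @return Numeric vector of length `n_coeff` (quefrencies `0..n_coeff-1`).
#' @export
real_cepstrum <- function(x, rate_hz, n_coeff = 13, floor_eps = 1e-10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * n_coeff) stop("series too short for n_coeff coefficients")
  logmag <- log(pmax(Mod(fft(x)), floor_eps))
  ceps <- Re(fft(logmag, inverse = TRUE)) / n
  ceps[seq_len(n_coeff)]
}

#' Summary statistics of a power spectrum
#'
#' @param spectrum a `pcg_spectrum` with nonzero total power.
#' @return List with `centroid_hz` (power-weighted mean frequency),
#'   `bandwidth_hz` (power-weighted standard deviation), `flatness`
#'   (geometric over arithmetic mean of power, in `[0, 1]`) and
#'   `rolloff95_hz` (smallest frequency with 95% cumulative power).
#' @export
spectral_summary <- function(spectrum) {
  f <- spectrum$freqs_hz
  p <- spectrum$power
  tot <- sum(p)
  if (tot <= 0) stop("degenerate input: all-zero spectrum")
  centroid <- sum(f * p) / tot
  bw <- sqrt(sum((f - centroid)^2 * p) / tot)
  pn <- p[p > 0]
  flat <- exp(mean(log(pn))) / mean(pn)
  rolloff <- f[which(cumsum(p) >= 0.95 * tot)[1]]
  list(centroid_hz = centroid, bandwidth_hz = bw,
       flatness = min(1, flat), rolloff95_hz = rolloff)
}

#' Acoustic feature bank for one series
#'
#' Classical linear features: log band powers over octave-spaced edges,
#' spectral centroid/bandwidth/flatness/rolloff, and low-quefrency cepstral
#' coefficients.
#'
#' @param x numeric series (a preprocessed recording).
#' @param rate_hz sampling rate of `x`.
#' @param band_edges_hz band edges for [band_powers()].
#' @param n_cep number of cepstral coefficients beyond the zeroth.
#' @return Named list of acoustic features.
#' @export
acoustic_features <- function(x, rate_hz,
                              band_edges_hz = c(25, 50, 100, 200, 400, 800),
                              n_cep = 6) {
  band_edges_hz <- band_edges_hz[band_edges_hz < rate_hz / 2]
  spec <- power_spectrum(x, rate_hz)
  bp <- band_powers(spec, band_edges_hz)
  ss <- spectral_summary(spec)
  cep <- real_cepstrum(x, rate_hz, n_coeff = n_cep + 1)
  out <- as.list(bp$log10_power)
  names(out) <- sprintf("bandpow_%g_%g", bp$band_low, bp$band_high)
  out$centroid_hz <- ss$centroid_hz
  out$bandwidth_hz <- ss$bandwidth_hz
  out$flatness <- ss$flatness
  out$rolloff95_hz <- ss$rolloff95_hz
  for (i in seq_len(n_cep)) out[[sprintf("cep_%d", i)]] <- cep[i + 1]
  out
}
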