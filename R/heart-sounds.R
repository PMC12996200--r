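#' Heart-sound synthesis parameters
#'
#' Describes one subject's phonocardiogram generator: beat timing, the S1/S2
#' valve-closure tone bursts, and an optional systolic murmur modelled as
#' band-limited noise under a shaping envelope — the simplest construction
#' consistent with murmurs arising from turbulent flow, with
#' `murmur_gain` as a severity dial.
#'
#' @param heart_rate_bpm mean heart rate, beats per minute, in (30, 200).
#' @param rr_jitter_frac multiplicative RR-interval jitter fraction in `[0, 1)`.
#' @param s1_freqs_hz,s2_freqs_hz component frequencies of the S1 and S2 bursts.
#' @param murmur_gain murmur amplitude scale (>= 0); 0 disables the murmur.
#' @param murmur_band_hz `(low, high)` murmur noise band in Hz.
#' @param murmur_envelope `"none"`, `"crescendo_decrescendo"` (ejection-type,
#'   e.g. aortic stenosis) or `"holosystolic"` (regurgitant-type).
#' @param noise_rms RMS of additive broadband background noise.
#' @return A `heart_sound_params` list.
#' @export
heart_sound_params <- function(heart_rate_bpm = 72, rr_jitter_frac = 0.05,
                               s1_freqs_hz = c(35, 70, 105),
                               s2_freqs_hz = c(55, 90, 140),
                               murmur_gain = 0,
                               murmur_band_hz = c(150, 600),
                               murmur_envelope = c("crescendo_decrescendo",
                                                   "holosystolic", "none"),
                               noise_rms = 0.02) {
  murmur_envelope <- match.arg(murmur_envelope)
  if (heart_rate_bpm <= 30 || heart_rate_bpm >= 200) {
    stop("heart_rate_bpm must lie in (30, 200)")
  }
  if (rr_jitter_frac < 0 || rr_jitter_frac >= 1) {
    stop("rr_jitter_frac must lie in [0, 1)")
  }
  if (murmur_gain < 0) stop("murmur_gain must be >= 0")
  if (length(murmur_band_hz) != 2 || murmur_band_hz[1] >= murmur_band_hz[2]) {
    stop("murmur_band_hz must satisfy low < high")
  }
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_frac = rr_jitter_frac,
                 s1_freqs_hz = s1_freqs_hz, s2_freqs_hz = s2_freqs_hz,
                 murmur_gain = murmur_gain, murmur_band_hz = murmur_band_hz,
                 murmur_envelope = murmur_envelope, noise_rms = noise_rms),
            class = "heart_sound_params")
}

#' Synthesize a phonocardiogram recording
#'
#' Places heartbeats by jittered RR intervals; each beat carries an S1 burst
#' at onset and an S2 burst at end-systole (systole occupies 35% of the RR
#' interval), both built from exponentially decaying windowed tones. The
#' murmur is band-limited Gaussian noise shaped by the systolic envelope and
#' scaled by `murmur_gain` (unit gain corresponds to a murmur RMS of 0.15
#' within systole, comparable to the S1 peak); broadband noise is added at
#' `noise_rms`. The murmur noise track is drawn even when `murmur_gain = 0`
#' so that recordings differing only in gain share all other components at a
#' fixed seed.
#'
#' @param hs_params a [heart_sound_params()].
#' @param duration_s clip length, seconds (> 0).
#' @param rate_hz sampling rate, >= 2000 Hz.
#' @param seed integer seed; fixed seed reproduces the clip exactly.
#' @param subject_id,site,source tags attached to the recording.
#' @return A `pcg_recording` with `round(duration_s * rate_hz)` samples in
#'   `[-1, 1]`.
#' @export
synthesize_pcg <- function(hs_params, duration_s = 30, rate_hz = 4000,
                           seed = 0L, subject_id = "S000", site = "aortic",
                           source = "personnel") {
  stopifnot(inherits(hs_params, "heart_sound_params"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (rate_hz < 2000) stop("rate_hz must be >= 2000")
  if (hs_params$murmur_band_hz[2] >= rate_hz / 2) {
    stop("murmur band extends above the Nyquist frequency")
  }
  n <- round(duration_s * rate_hz)
  p <- hs_params
  withr::with_seed(seed, {
    rr0 <- 60 / p$heart_rate_bpm
    onsets <- numeric(0)
    t0 <- 0.1
    while (t0 < duration_s) {
      onsets <- c(onsets, t0)
      t0 <- t0 + rr0 * (1 + p$rr_jitter_frac * runif(1, -1, 1))
    }
    x <- numeric(n)
    env <- numeric(n)
    sys_dur <- 0.35 * rr0
    for (ons in onsets) {
      x <- add_burst(x, rate_hz, ons, p$s1_freqs_hz, amp = 0.5)
      x <- add_burst(x, rate_hz, ons + sys_dur, p$s2_freqs_hz, amp = 0.35)
      if (p$murmur_envelope != "none") {
        env <- add_envelope(env, rate_hz, ons + 0.04, ons + sys_dur - 0.01,
                            p$murmur_envelope)
      }
    }
    murmur_src <- rnorm(n)
    murmur <- fft_bandpass(murmur_src, rate_hz, p$murmur_band_hz[1],
                           p$murmur_band_hz[2], trans = 20)
    murmur <- murmur / sqrt(mean(murmur^2))
    x <- x + p$murmur_gain * 0.15 * env * murmur
    x <- x + rnorm(n, sd = p$noise_rms)
  })
  peak <- max(abs(x))
  if (peak > 1) x <- x * (0.99 / peak)
  new_recording(samples = x, rate_hz = rate_hz, site = site, source = source,
                subject_id = subject_id)
}

add_burst <- function(x, rate, t0, freqs, amp, dur = 0.11, decay = 0.025) {
  n <- length(x)
  i0 <- floor(t0 * rate) + 1
  i1 <- min(n, floor((t0 + dur) * rate))
  if (i0 > n || i1 < i0) return(x)
  tt <- ((i0:i1) - 1) / rate - t0
  w <- exp(-tt / decay) * sin(pi * tt / dur)^2
  tone <- rep(0, length(tt))
  for (f in freqs) tone <- tone + sin(2 * pi * f * tt)
  x[i0:i1] <- x[i0:i1] + amp * w * tone / length(freqs)
  x
}

add_envelope <- function(env, rate, t_start, t_end, shape) {
  n <- length(env)
  i0 <- max(1, floor(t_start * rate) + 1)
  i1 <- min(n, floor(t_end * rate))
  if (i1 <= i0) return(env)
  s <- seq(0, 1, length.out = i1 - i0 + 1)
  v <- switch(shape,
    crescendo_decrescendo = sin(pi * s)^2,
    holosystolic = {
      # flat with 10% cosine tapers at both ends
      taper <- pmin(1, pmin(s, 1 - s) / 0.1)
      0.5 - 0.5 * cos(pi * taper)
    })
  env[i0:i1] <- pmax(env[i0:i1], v)
  env
}
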