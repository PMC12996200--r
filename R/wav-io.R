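#' Read a WAV file into a recording
#'
#' Parses RIFF/WAVE with integer PCM (16/24/32-bit) or IEEE float32 samples.
#' Integer PCM is scaled to `[-1, 1]` by the format's full-scale maximum
#' (2^15 - 1, 2^23 - 1, 2^31 - 1), so a full-scale code round-trips to
#' exactly 1. Multi-channel files are reduced to the first channel with a
#' warning. Auscultation tags are parsed from the
#' `<subject>_<site>_<source>.wav` filename convention unless given
#' explicitly.
#'
#' @param path file path.
#' @param subject_id,site,source optional tag overrides; `site` is
#'   `"aortic"` or `"axillary"`, `source` is `"personnel"` or `"subject"`.
#' @return A `pcg_recording`: list with `samples`, `rate_hz`, `site`,
#'   `source`, `subject_id`.
#' @export
read_wav <- function(path, subject_id = NULL, site = NULL, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 12 ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    stop("format error: not a RIFF/WAVE file: ", basename(path))
  }
  pos <- 13L
  fmt <- NULL; data_raw <- NULL
  while (pos + 8 <= length(raw) + 1) {
    id <- rawToChar(raw[pos:(pos + 3)])
    size <- read_u32(raw, pos + 4L)
    body_start <- pos + 8L
    if (body_start + size - 1 > length(raw)) {
      if (id == "data") size <- length(raw) - body_start + 1L else {
        stop("format error: truncated chunk in ", basename(path))
      }
    }
    if (id == "fmt ") fmt <- raw[body_start:(body_start + size - 1)]
    if (id == "data") data_raw <- raw[body_start:(body_start + size - 1)]
    pos <- body_start + size + (size %% 2L)
  }
  if (is.null(fmt) || length(fmt) < 16) {
    stop("format error: missing fmt chunk in ", basename(path))
  }
  if (is.null(data_raw)) stop("format error: missing data chunk in ", basename(path))
  audio_format <- read_u16(fmt, 1L)
  channels <- read_u16(fmt, 3L)
  rate <- read_u32(fmt, 5L)
  bits <- read_u16(fmt, 15L)
  if (audio_format == 65534L && length(fmt) >= 26) {
    audio_format <- read_u16(fmt, 25L)  # WAVE_FORMAT_EXTENSIBLE subformat
  }
  x <- decode_samples(data_raw, audio_format, bits, basename(path))
  if (channels > 1) {
    warning("taking first of ", channels, " channels: ", basename(path))
    x <- x[seq(1, length(x), by = channels)]
  }
  if (is.null(subject_id) || is.null(site) || is.null(source)) {
    tags <- parse_wav_tags(basename(path))
  } else {
    tags <- list(subject_id = NULL, site = NULL, source = NULL)
  }
  new_recording(samples = x, rate_hz = rate,
                site = site %||% tags$site,
                source = source %||% tags$source,
                subject_id = subject_id %||% tags$subject_id)
}

decode_samples <- function(data_raw, audio_format, bits, fname) {
  n_bytes <- length(data_raw)
  # integer PCM is scaled by the format maximum (2^(bits-1) - 1), so the
  # full-scale code +max reads back as exactly +1; the single code below
  # -max is clamped to -1
  if (audio_format == 3L) {
    if (bits != 32) stop("format error: unsupported float width in ", fname)
    readBin(data_raw, "numeric", n = n_bytes %/% 4, size = 4, endian = "little")
  } else if (audio_format == 1L) {
    if (bits == 16) {
      pmax(-1, readBin(data_raw, "integer", n = n_bytes %/% 2, size = 2,
                       signed = TRUE, endian = "little") / 32767)
    } else if (bits == 24) {
      m <- n_bytes %/% 3
      b <- matrix(as.integer(data_raw[seq_len(3 * m)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      pmax(-1, v / 8388607)
    } else if (bits == 32) {
      pmax(-1, readBin(data_raw, "integer", n = n_bytes %/% 4, size = 4,
                       endian = "little") / 2147483647)
    } else {
      stop("format error: unsupported PCM width ", bits, " in ", fname)
    }
  } else {
    stop("format error: unsupported/compressed audio format code ",
         audio_format, " in ", fname)
  }
}

#' Write a recording to a WAV file
#'
#' Samples outside `[-1, 1]` are clipped with a warning. For integer PCM,
#' `+1.0` maps to the format maximum (32767 / 8388607). Float32 output
#' round-trips bit-exactly through [read_wav()].
#'
#' @param recording a `pcg_recording`.
#' @param path output path.
#' @param bit_depth `"pcm16"`, `"pcm24"` or `"float32"`.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(recording, path, bit_depth = c("pcm16", "pcm24", "float32")) {
  bit_depth <- match.arg(bit_depth)
  x <- as.numeric(recording$samples)
  if (any(abs(x) > 1)) {
    warning("samples outside [-1, 1] clipped on write")
    x <- pmin(1, pmax(-1, x))
  }
  rate <- as.integer(round(recording$rate_hz))
  n <- length(x)
  bytes_per <- switch(bit_depth, pcm16 = 2L, pcm24 = 3L, float32 = 4L)
  fmt_code <- if (bit_depth == "float32") 3L else 1L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")       # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")  # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else if (bit_depth == "pcm24") {
    v <- as.integer(round(x * 8388607))
    v <- ifelse(v < 0, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

new_recording <- function(samples, rate_hz, site, source, subject_id) {
  if (length(samples) < 1) stop("recording must contain at least one sample")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 site = site, source = source, subject_id = subject_id),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s  %s/%s  %.1f s @ %g Hz\n",
              x$subject_id %||% "?", x$site %||% "?", x$source %||% "?",
              length(x$samples) / x$rate_hz, x$rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `pcg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$rate_hz
}

parse_wav_tags <- function(fname) {
  m <- regmatches(fname,
    regexec("^(.+)_(aortic|axillary)_(personnel|subject)\\.wav$", fname))[[1]]
  if (length(m) == 4) {
    list(subject_id = m[2], site = m[3], source = m[4])
  } else {
    warning("filename does not follow <subject>_<site>_<source>.wav: ", fname)
    list(subject_id = sub("\\.wav$", "", fname), site = NA_character_,
         source = NA_character_)
  }
}

read_u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

read_u32 <- function(raw, pos) {
  lo <- read_u16(raw, pos)
  hi <- read_u16(raw, pos + 2L)
  lo + 65536 * hi
}
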