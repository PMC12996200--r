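test_that("16-bit PCM round-trip stays within the quantization bound", {
  x <- sin(2 * pi * 100 * (0:3999) / 4000) * 0.9
  rec <- make_rec(x)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path, "pcm16")
  back <- read_wav(path, subject_id = "S001", site = "aortic",
                   source = "personnel")
  expect_equal(back$rate_hz, 4000)
  expect_lt(max(abs(back$samples - x)), 2^-15)
})

test_that("float32 output round-trips bit-exactly and preserves duration", {
  x <- as.numeric(runif(120000, -1, 1))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(make_rec(x), path, "float32")
  back <- read_wav(path, subject_id = "S001", site = "aortic",
                   source = "personnel")
  expect_equal(back$samples, x, tolerance = 2^-23)
  expect_equal(recording_duration(back), 30.0)
  # a second round trip of the float32 representation is bit-exact
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(back, path2, "float32")
  back2 <- read_wav(path2, subject_id = "S001", site = "aortic",
                    source = "personnel")
  expect_identical(back2$samples, back$samples)
})

test_that("24-bit PCM round-trip stays within its quantization bound", {
  x <- seq(-1, 1, length.out = 1000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(make_rec(x), path, "pcm24")
  back <- read_wav(path, subject_id = "S001", site = "aortic",
                   source = "personnel")
  expect_lt(max(abs(back$samples - x)), 2^-23)
})

test_that("full-scale +1 maps to the 16-bit format maximum", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(make_rec(c(1, -1, 0)), path, "pcm16")
  raw <- readBin(path, "raw", file.size(path))
  v <- readBin(raw[45:50], "integer", n = 3, size = 2, endian = "little")
  expect_equal(v, c(32767, -32767, 0))
})

test_that("out-of-range samples are clipped with a warning", {
  path <- withr::local_tempfile(fileext = ".wav")
  expect_warning(write_wav(make_rec(c(0.5, 1.7, -2)), path, "pcm16"),
                 "clipped")
  back <- read_wav(path, subject_id = "S001", site = "aortic",
                   source = "personnel")
  expect_equal(back$samples[2:3], c(1, -1), tolerance = 1e-4)
})

test_that("truncated or non-WAV input raises a format error, not a crash", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(make_rec(rnorm(100) / 5), path, "pcm16")
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:20], path)
  expect_error(read_wav(path), "format error")
  writeBin(charToRaw("definitely not audio data"), path)
  expect_error(read_wav(path), "format error")
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
})

test_that("tags are parsed from the filename convention", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "S042_axillary_subject.wav")
  write_wav(make_rec(rnorm(50) / 5), path, "float32")
  rec <- read_wav(path)
  expect_equal(rec$subject_id, "S042")
  expect_equal(rec$site, "axillary")
  expect_equal(rec$source, "subject")
})

test_that("a cohort survives a write/load round trip", {
  cfg <- cohort_config(group_sizes = c(AS = 2, MR = 1, SHD_other = 1,
                                       control = 2),
                       duration_s = 1, rate_hz = 2000, seed = 5)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- load_cohort(dir)
  expect_equal(nrow(back$subjects), 6)
  expect_length(back$recordings, 18)
  orig <- cohort$recordings[[1]]
  match_idx <- which(sapply(back$recordings, function(r) {
    r$subject_id == orig$subject_id && r$site == orig$site &&
      r$source == orig$source
  }))
  expect_equal(back$recordings[[match_idx]]$samples, orig$samples,
               tolerance = 1e-6)
})
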