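rms_of <- function(w) sqrt(mean(w$samples^2))

test_that("to_mono averages channels", {
  x <- sin(2 * pi * 3 * seq(0, 1, length.out = 1000))
  same <- waveform(rbind(x, x), 1000)
  expect_equal(to_mono(same)$samples, x)
  opp <- waveform(rbind(x, -x), 1000)
  expect_equal(to_mono(opp)$samples, rep(0, 1000))
  mono <- waveform(x, 1000)
  expect_identical(to_mono(mono), mono)
  expect_error(to_mono(waveform(matrix(numeric(0), 0, 0), 1000)), "channels")
})

test_that("resampling preserves duration and tone frequency", {
  w <- waveform(rnorm(32000), 32000)
  r <- resample_wave(w, 16384)
  expect_equal(length(r), 16384)
  expect_equal(r$rate, 16384)
  expect_identical(resample_wave(w, 32000), w)
  expect_error(resample_wave(w, -1), "positive")

  # 100 Hz sine: dominant DFT bin survives 32000 -> 16384 Hz
  s <- sine_wave(100, rate = 32000)
  rs <- resample_wave(s, 16384)
  spec <- Mod(stats::fft(rs$samples))[1:(length(rs) %/% 2)]
  peak_hz <- (which.max(spec) - 1) * 16384 / length(rs)
  bin_hz <- 16384 / length(rs)
  expect_lt(abs(peak_hz - 100), bin_hz + 1e-9)
})

test_that("silence trimming gates only leading and trailing frames", {
  cfg <- preprocess_config()
  silent <- waveform(rep(0, 16384), 16384)
  expect_equal(length(remove_silence(silent, cfg)), 0)

  tone <- 0.5 * sin(2 * pi * 300 * seq(0, 2, length.out = 2 * 16384))
  padded <- waveform(c(rep(0, 16384), tone, rep(0, 16384)), 16384)
  trimmed <- remove_silence(padded, cfg)
  expect_lt(abs(length(trimmed) - 2 * 16384), cfg$hop + cfg$frame_len)

  pure <- waveform(tone, 16384)
  expect_equal(remove_silence(pure, cfg)$samples, tone)
})

test_that("band-pass keeps the bee band and rejects out-of-band energy", {
  cfg <- preprocess_config()
  pass <- sine_wave(300)
  out <- bandpass(pass, cfg)
  expect_equal(length(out), length(pass))
  expect_gte(rms_of(out), 0.9 * rms_of(pass))

  stop3k <- sine_wave(3000)
  atten_db <- 20 * log10(rms_of(bandpass(stop3k, cfg)) / rms_of(stop3k))
  expect_lte(atten_db, -12)

  dc <- waveform(rep(0.7, 16384), 16384)
  expect_lte(rms_of(bandpass(dc, cfg)), 0.01 * 0.7)
})

test_that("segmentation follows the pad/drop tail policy", {
  cfg <- preprocess_config()
  w <- function(n) waveform(rnorm(n), 16384, label = "QueenPresent")
  expect_equal(length(segment_wave(w(163840), cfg)), 10)

  s2 <- segment_wave(w(24000), cfg)           # remainder 7616 >= 4096: pad
  expect_equal(length(s2), 2)
  expect_equal(s2$segments[(24000 - 16384 + 1):16384, 2],
               rep(0, 16384 - (24000 - 16384)))

  expect_equal(length(segment_wave(w(20000), cfg)), 1)  # 3616 < 4096: drop
  expect_true(all(segment_wave(w(163840), cfg)$labels == "QueenPresent"))
})

test_that("full pipeline composes deterministically on fixture clips", {
  fx <- fixture_config(rate = 32000, duration = 10)
  clip <- gen_clip("QueenAbsent", fx, seed = 4)
  cfg <- preprocess_config()
  s1 <- preprocess_pipeline(list(clip), "QueenAbsent", cfg)
  expect_s3_class(s1, "segment_set")
  expect_equal(length(s1), 10)
  expect_equal(nrow(s1$segments), 16384)
  expect_equal(s1$rate, 16384)

  # identical input + config -> identical segments
  s2 <- preprocess_pipeline(list(clip), "QueenAbsent", cfg)
  expect_identical(s1$segments, s2$segments)

  # 2 s of leading silence disappears
  padded <- waveform(c(rep(0, 64000), clip$samples[1:(8 * 32000)]),
                     32000, label = "QueenAbsent")
  s3 <- preprocess_pipeline(list(padded), "QueenAbsent", cfg)
  expect_equal(length(s3), 8)

  # an all-silent file is skipped; alone it is an error
  silent <- waveform(rep(0, 32000), 32000)
  expect_error(suppressMessages(preprocess_pipeline(list(silent), "NoBee", cfg)),
               "no segments")
  both <- suppressMessages(preprocess_pipeline(list(clip, silent),
                                               c("QueenAbsent", "NoBee"), cfg))
  expect_equal(length(both), 10)
})
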