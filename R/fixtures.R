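#' Synthetic hive-audio fixture configuration
#'
#' Parameters of the three-class synthetic dataset the package uses to
#' exercise the whole pipeline without any external recordings. The two bee
#' classes are harmonic stacks (fundamental times a decaying harmonic series,
#' capped below 2 kHz) under a slow amplitude-modulation envelope plus
#' band-limited noise; `NoBee` is low-pass-shaped noise with no harmonic
#' line structure. All acoustic parameters are invented fixture choices made
#' so the classes are separable by MFCC features; they are not measurements
#' of real hives.
#'
#' @param rate sampling rate in Hz (default 32000, the raw-recording rate).
#' @param duration clip duration in seconds (default 10).
#' @param fundamental named numeric: per-class fundamental in Hz
#'   (QueenPresent 250, QueenAbsent 330).
#' @param n_harmonics harmonics per stack (default 7; harmonics at or above
#'   2 kHz are dropped).
#' @param harmonic_decay amplitude ratio between successive harmonics
#'   (default 0.7).
#' @param am_rate named numeric: per-class amplitude-modulation rate in Hz
#'   (QueenPresent 4, QueenAbsent 9).
#' @param noise_snr_db signal-to-noise ratio in dB for the bee classes
#'   (default 10); `NoBee` clips are noise only.
#' @param f0_jitter relative standard deviation of the per-clip fundamental
#'   (default 0.05), emulating natural pitch variability between
#'   recordings.
#' @param snr_jitter_db standard deviation of the per-clip SNR in dB
#'   (default 2).
#' @param am_depth_range range of the per-clip amplitude-modulation depth
#'   (default 0.3 to 0.7).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(rate = 32000, duration = 10,
                           fundamental = c(QueenPresent = 250, QueenAbsent = 330),
                           n_harmonics = 7, harmonic_decay = 0.7,
                           am_rate = c(QueenPresent = 4, QueenAbsent = 9),
                           noise_snr_db = 10, f0_jitter = 0.05,
                           snr_jitter_db = 2, am_depth_range = c(0.3, 0.7)) {
  if (duration <= 1) stopf("fixture duration must exceed 1 s")
  structure(list(rate = rate, duration = duration, fundamental = fundamental,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay, am_rate = am_rate,
                 noise_snr_db = noise_snr_db, f0_jitter = f0_jitter,
                 snr_jitter_db = snr_jitter_db,
                 am_depth_range = am_depth_range),
            class = "fixture_config")
}

#' Generate one synthetic hive-audio clip
#'
#' Deterministic given `(label, cfg, seed)`. Bee classes are a harmonic
#' stack (all partials below 2 kHz) with amplitude modulation and additive
#' band-limited noise at `noise_snr_db`; `NoBee` is low-pass-shaped noise.
#' The clip is peak-normalized to 0.9.
#'
#' @param label one of `"QueenPresent"`, `"QueenAbsent"`, `"NoBee"`.
#' @param cfg a [fixture_config].
#' @param seed integer seed for this clip's noise realization.
#' @return A [waveform] with the given label.
#' @export
gen_clip <- function(label, cfg = fixture_config(), seed = 1L) {
  if (!label %in% EVENT_LABELS)
    stopf("unknown event label '%s'", label)
  n <- round(cfg$rate * cfg$duration)
  t <- (seq_len(n) - 1L) / cfg$rate
  with_seed(derive_seed(seed, "fixture", label), {
    if (label == "NoBee") {
      x <- lowpass_noise(n, cfg$rate, cutoff = 1500)
    } else {
      # per-clip variability: detuned fundamental, jittered SNR, AM depth
      f0 <- cfg$fundamental[[label]] *
        exp(stats::rnorm(1, 0, cfg$f0_jitter))
      ks <- seq_len(cfg$n_harmonics)
      ks <- ks[f0 * ks < 2000]                 # keep energy below 2 kHz
      amps <- cfg$harmonic_decay^(ks - 1)
      phases <- stats::runif(length(ks), 0, 2 * pi)
      x <- numeric(n)
      for (j in seq_along(ks))
        x <- x + amps[j] * sin(2 * pi * f0 * ks[j] * t + phases[j])
      depth <- stats::runif(1, cfg$am_depth_range[1], cfg$am_depth_range[2])
      am <- 1 + depth * sin(2 * pi * cfg$am_rate[[label]] * t +
                              stats::runif(1, 0, 2 * pi))
      x <- x * am
      snr <- cfg$noise_snr_db + stats::rnorm(1, 0, cfg$snr_jitter_db)
      noise <- lowpass_noise(n, cfg$rate, cutoff = 1800)
      noise <- noise * rms(x) / rms(noise) * 10^(-snr / 20)
      x <- x + noise
    }
    x <- 0.9 * x / max(abs(x))
    waveform(x, cfg$rate, source_id = sprintf("fixture_%s_%d", label, seed),
             label = label)
  })
}

# White noise shaped by a 4th-order Butterworth low-pass, so its energy sits
# below `cutoff` like real hive noise sits below 2 kHz.
#' @keywords internal
lowpass_noise <- function(n, rate, cutoff) {
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filter(bf, stats::rnorm(n)))
}

#' Generate a labeled synthetic dataset of standardized segments
#'
#' Draws `n_per_class` clips per class (or class counts proportional to
#' `ratio`), runs the full [preprocess_pipeline] on them, and returns the
#' resulting standardized one-second segments.
#'
#' @param n_per_class clips per class, or total clips when `ratio` is given.
#' @param cfg a [fixture_config].
#' @param seed master seed; per-clip streams are derived from
#'   `(seed, label, clip index)` so generation order does not matter.
#' @param classes which labels to generate (default all three).
#' @param ratio optional numeric vector (same length as `classes`) of class
#'   proportions, e.g. `c(40, 20, 40)`; counts are `round(n_per_class *
#'   ratio / sum(ratio))`.
#' @param pre a [preprocess_config] for the standardization step.
#' @return A [segment_set].
#' @export
gen_dataset <- function(n_per_class, cfg = fixture_config(), seed = 1L,
                        classes = EVENT_LABELS, ratio = NULL,
                        pre = preprocess_config()) {
  stopifnot(n_per_class >= 1)
  counts <- if (is.null(ratio)) rep(n_per_class, length(classes))
            else round(n_per_class * ratio / sum(ratio))
  waves <- list(); labels <- character(0)
  for (ci in seq_along(classes)) {
    for (k in seq_len(counts[ci])) {
      waves[[length(waves) + 1L]] <-
        gen_clip(classes[ci], cfg, seed = derive_seed(seed, classes[ci], k))
      labels <- c(labels, classes[ci])
    }
  }
  preprocess_pipeline(waves, labels, pre)
}
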