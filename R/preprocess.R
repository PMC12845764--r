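#' Preprocessing configuration
#'
#' Settings for the deterministic conversion of raw hive recordings into
#' standardized one-second clips: downsample to `target_rate`, mix to mono,
#' trim leading/trailing silence, band-pass to the bee-relevant band, then
#' cut into fixed-length segments.
#'
#' @param target_rate output sampling rate in Hz (default 16384).
#' @param band_low,band_high band-pass edges in Hz (defaults 20 and 2000);
#'   must satisfy `0 < band_low < band_high < target_rate / 2`.
#' @param segment_len segment length in samples (default 16384, i.e. 1 s).
#' @param silence_floor_db frame-RMS threshold in dB relative to the file's
#'   peak frame RMS below which leading/trailing frames count as silence
#'   (default -40).
#' @param min_tail_fraction fraction of `segment_len` below which a final
#'   partial segment is dropped rather than zero-padded (default 0.25).
#' @param frame_len,hop analysis frame length and hop (samples) for the
#'   silence gate (defaults 1024 and 512).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 16384, band_low = 20,
                              band_high = 2000, segment_len = 16384,
                              silence_floor_db = -40,
                              min_tail_fraction = 0.25,
                              frame_len = 1024L, hop = 512L) {
  if (!(band_low > 0 && band_low < band_high && band_high < target_rate / 2))
    stopf("band edges must satisfy 0 < band_low < band_high < target_rate/2")
  if (segment_len <= 0) stopf("segment_len must be positive")
  if (min_tail_fraction < 0 || min_tail_fraction > 1)
    stopf("min_tail_fraction must lie in [0, 1]")
  structure(list(target_rate = target_rate, band_low = band_low,
                 band_high = band_high, segment_len = as.integer(segment_len),
                 silence_floor_db = silence_floor_db,
                 min_tail_fraction = min_tail_fraction,
                 frame_len = as.integer(frame_len), hop = as.integer(hop)),
            class = "preprocess_config")
}

#' Mix a waveform down to mono
#'
#' Channel-mean mixdown; mono input is returned unchanged.
#' @param w a [waveform].
#' @return A mono [waveform].
#' @export
to_mono <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (!is.matrix(w$samples)) return(w)
  if (nrow(w$samples) == 0L) stopf("waveform has zero channels")
  waveform(colMeans(w$samples), w$rate, w$source_id, w$label)
}

#' Resample a waveform
#'
#' Band-limited polyphase resampling (via [signal::resample]); the exact
#' 32000 -> 16384 Hz conversion used for hive recordings is the rational
#' ratio 64:125. Duration is preserved to within one sample.
#'
#' @param w a mono [waveform].
#' @param target_rate desired rate in Hz.
#' @return A [waveform] at `target_rate`.
#' @export
resample_wave <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"))
  if (target_rate <= 0) stopf("target_rate must be positive")
  if (target_rate == w$rate) return(w)
  g0 <- gcd_int(round(target_rate), round(w$rate))
  p <- round(target_rate) / g0
  q <- round(w$rate) / g0
  y <- signal::resample(w$samples, p, q)
  n_out <- round(length(w$samples) * target_rate / w$rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, numeric(n_out - length(y)))
  waveform(y, target_rate, w$source_id, w$label)
}

#' @keywords internal
gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Trim leading and trailing silence
#'
#' Frames the signal (`frame_len`/`hop` from `cfg`), computes per-frame RMS,
#' and removes leading and trailing frames whose RMS falls below the file's
#' peak frame RMS plus `silence_floor_db`. Interior quiet frames are kept, so
#' the clip still "starts and ends with an active bee sound" without interior
#' edits. An all-silent input yields an empty waveform.
#'
#' @param w a mono [waveform].
#' @param cfg a [preprocess_config].
#' @return A [waveform], possibly empty.
#' @export
remove_silence <- function(w, cfg = preprocess_config()) {
  stopifnot(inherits(w, "waveform"))
  if (is.matrix(w$samples)) stopf("remove_silence expects mono audio")
  x <- w$samples
  if (length(x) == 0L)
    return(waveform(numeric(0), w$rate, w$source_id, w$label))
  fr <- frame_signal(x, cfg$frame_len, cfg$hop)
  if (ncol(fr) == 0L) {                 # shorter than one frame: gate whole clip
    keep <- rms(x) > 0
    return(waveform(if (keep) x else numeric(0), w$rate, w$source_id, w$label))
  }
  frame_rms <- sqrt(colMeans(fr^2))
  peak <- max(frame_rms)
  if (peak == 0)
    return(waveform(numeric(0), w$rate, w$source_id, w$label))
  active <- 20 * log10(pmax(frame_rms, .Machine$double.xmin) / peak) >
    cfg$silence_floor_db
  if (!any(active))
    return(waveform(numeric(0), w$rate, w$source_id, w$label))
  first <- which(active)[1]
  last <- which(active)[length(which(active))]
  from <- (first - 1L) * cfg$hop + 1L
  to <- min(length(x), (last - 1L) * cfg$hop + cfg$frame_len)
  waveform(x[from:to], w$rate, w$source_id, w$label)
}

#' Band-pass filter a waveform
#'
#' Zero-phase 4th-order Butterworth band-pass (two poles per edge, applied
#' forward and backward with [signal::filtfilt]), so passband timing is
#' undistorted. Output length equals input length.
#'
#' @param w a mono [waveform].
#' @param cfg a [preprocess_config] giving `band_low` / `band_high`.
#' @return The filtered [waveform].
#' @export
bandpass <- function(w, cfg = preprocess_config()) {
  stopifnot(inherits(w, "waveform"))
  if (!(cfg$band_low > 0 && cfg$band_high > cfg$band_low &&
        cfg$band_high < w$rate / 2))
    stopf("band edges invalid for rate %.0f Hz", w$rate)
  if (length(w$samples) == 0L) return(w)
  bf <- signal::butter(2, c(cfg$band_low, cfg$band_high) / (w$rate / 2),
                       type = "pass")
  # demean and odd-reflect the edges so the zero-phase pass starts near
  # steady state (suppresses DC/step transients at the clip boundaries)
  x <- w$samples - mean(w$samples)
  n <- length(x)
  p <- min(n - 1L, 1024L)
  if (p > 0L) {
    xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
    y <- signal::filtfilt(bf, xp)[(p + 1L):(p + n)]
  } else y <- signal::filtfilt(bf, x)
  waveform(y, w$rate, w$source_id, w$label)
}

#' Cut a waveform into fixed-length segments
#'
#' Non-overlapping consecutive windows of `segment_len` samples. A final
#' partial window is zero-padded to full length when its valid fraction is at
#' least `min_tail_fraction`, and dropped otherwise. The waveform's label is
#' propagated to every segment.
#'
#' @param w a mono [waveform] at the target rate.
#' @param cfg a [preprocess_config].
#' @return A [segment_set] (possibly with zero segments).
#' @export
segment_wave <- function(w, cfg = preprocess_config()) {
  stopifnot(inherits(w, "waveform"))
  L <- cfg$segment_len
  n <- length(w$samples)
  n_full <- n %/% L
  rem <- n - n_full * L
  keep_tail <- rem >= cfg$min_tail_fraction * L
  n_seg <- n_full + as.integer(keep_tail)
  if (n_seg == 0L)
    return(segment_set(matrix(numeric(0), nrow = L, ncol = 0), character(0),
                       w$rate, character(0), integer(0)))
  m <- matrix(0, nrow = L, ncol = n_seg)
  for (i in seq_len(n_full)) m[, i] <- w$samples[((i - 1L) * L + 1L):(i * L)]
  if (keep_tail) m[seq_len(rem), n_seg] <- w$samples[(n_full * L + 1L):n]
  segment_set(m, w$label, w$rate, source_id = w$source_id,
              segment_index = seq_len(n_seg))
}

#' Full preprocessing pipeline
#'
#' For each file: load, mix to mono, resample to `target_rate`, trim
#' leading/trailing silence, band-pass, segment. Per-file failures are
#' logged (via `message`) and skipped; an empty final set is an error.
#'
#' @param paths character vector of WAV paths (or a list of [waveform]s).
#' @param labels event labels, one per input (recycled).
#' @param cfg a [preprocess_config].
#' @param verbose log one line per file with counts at each stage.
#' @return A [segment_set] combining all inputs.
#' @export
preprocess_pipeline <- function(paths, labels = NA_character_,
                                cfg = preprocess_config(), verbose = FALSE) {
  if (length(paths) == 0L) stopf("preprocess_pipeline: no inputs")
  labels <- rep_len(as.character(labels), length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch({
      w <- if (inherits(paths[[i]], "waveform")) {
        x <- paths[[i]]; x$label <- labels[i]; x
      } else load_wav(paths[[i]], label = labels[i])
      n_raw <- length(w)
      w <- to_mono(w)
      w <- resample_wave(w, cfg$target_rate)
      n_rs <- length(w)
      w <- remove_silence(w, cfg)
      n_trim <- length(w)
      w <- bandpass(w, cfg)
      s <- segment_wave(w, cfg)
      if (verbose)
        message(sprintf("[preprocess] %s: %d raw -> %d resampled -> %d trimmed -> %d segments",
                        w$source_id, n_raw, n_rs, n_trim, length(s)))
      s
    }, error = function(e) {
      message(sprintf("[preprocess] input %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    out[[i]] <- res
  }
  out <- Filter(function(s) !is.null(s) && length(s) > 0L, out)
  if (length(out) == 0L) stopf("preprocess_pipeline: no segments produced")
  do.call(c, out)
}
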