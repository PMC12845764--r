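#' Waveform objects
#'
#' A `waveform` is the package's basic audio container: a numeric vector (or,
#' before mixdown, a channels-by-samples matrix) of amplitudes nominally in
#' \[-1, 1\], together with its sampling rate, an opaque source identifier and
#' an optional hive-event label (`"QueenPresent"`, `"QueenAbsent"`, `"NoBee"`,
#' or the `"synthetic"` sentinel used for generated audio).
#'
#' @param samples numeric vector (mono) or matrix with one row per channel.
#' @param rate sampling rate in Hz; must be positive.
#' @param source_id opaque string identifying the origin of the audio.
#' @param label optional event label; `NA` when unknown.
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 250 * seq(0, 1, length.out = 16384)), 16384)
#' w
#' @export
waveform <- function(samples, rate, source_id = "", label = NA_character_) {
  if (!is.numeric(samples)) stopf("waveform samples must be numeric")
  if (!is.matrix(samples)) samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stopf("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stopf("waveform rate must be a single positive number")
  structure(list(samples = samples, rate = as.numeric(rate),
                 source_id = as.character(source_id),
                 label = as.character(label)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  ns <- if (is.matrix(x$samples)) ncol(x$samples) else length(x$samples)
  nch <- if (is.matrix(x$samples)) nrow(x$samples) else 1L
  cat(sprintf("<waveform> %d samples, %d channel(s), %.0f Hz (%.3f s)",
              ns, nch, x$rate, ns / x$rate))
  if (!is.na(x$label)) cat(", label:", x$label)
  if (nzchar(x$source_id)) cat(", source:", x$source_id)
  cat("\n")
  invisible(x)
}

#' @export
length.waveform <- function(x) {
  if (is.matrix(x$samples)) ncol(x$samples) else length(x$samples)
}

#' Number of channels of a waveform
#' @param w a `waveform`.
#' @return integer channel count.
#' @export
n_channels <- function(w) {
  if (is.matrix(w$samples)) nrow(w$samples) else 1L
}
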