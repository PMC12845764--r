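# Minimal RIFF/WAVE reader and writer.
#
# Supports the formats the pipeline actually meets: PCM16, PCM24 and IEEE
# float32, mono or multi-channel, little-endian. Integer samples are scaled
# to [-1, 1) by the usual 2^(bits-1) convention.

#' Read a WAV file
#'
#' Reads a PCM16, PCM24 or IEEE-float32 WAV file into a [waveform]. Integer
#' PCM samples are scaled by `2^(bits-1)` so full scale maps to \[-1, 1);
#' multi-channel audio is kept channel-major (one row per channel) until
#' [to_mono] is applied.
#'
#' @param path path to the file.
#' @param label optional event label attached to the result.
#' @return A [waveform]; `source_id` is the file name.
#' @export
load_wav <- function(path, label = NA_character_) {
  if (!file.exists(path)) stopf("cannot read WAV file '%s': no such file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stopf("cannot read WAV file '%s': not a RIFF file", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stopf("cannot read WAV file '%s': not a WAVE file", path)

  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                               endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
      break
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data) || length(data) == 0L)
    stopf("cannot read WAV file '%s': empty or malformed", path)

  nch <- fmt$n_channels
  x <- switch(as.character(fmt$audio_format),
    "1" = {                       # integer PCM
      if (fmt$bits == 16L) {
        readBin(data, "integer", length(data) / 2L, size = 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data) %/% 3L
        b <- matrix(as.integer(data[seq_len(3L * n)]), nrow = 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stopf("cannot read WAV file '%s': unsupported PCM bit depth %d",
                   path, fmt$bits)
    },
    "3" = readBin(data, "double", length(data) / 4L, size = 4,
                  endian = "little"),
    stopf("cannot read WAV file '%s': unsupported audio format %d",
          path, fmt$audio_format))

  if (nch > 1L) x <- matrix(x, nrow = nch)   # interleaved -> channel-major
  waveform(x, fmt$sample_rate, source_id = basename(path), label = label)
}

#' Write a waveform to a WAV file
#'
#' @param w a [waveform] (mono vector or channel-major matrix).
#' @param path output path.
#' @param bits `16` for PCM16 or `32` for IEEE float32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16L) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16L, 32L))
  x <- w$samples
  nch <- n_channels(w)
  if (is.matrix(x)) x <- as.numeric(x)      # column-major == interleaved
  if (bits == 16L) {
    pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    payload <- writeBin(pcm, raw(), size = 2, endian = "little")
    fmt_code <- 1L; block <- 2L * nch
  } else {
    payload <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
    fmt_code <- 3L; block <- 4L * nch
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}
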