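#' Labeled sets of fixed-length audio segments
#'
#' A `segment_set` holds the standardized clips every downstream stage works
#' on: a `segment_len x n` numeric matrix (one column per clip, all at the
#' same rate), a parallel label vector, and per-segment provenance
#' (`source_id`, `segment_index`).
#'
#' @param segments numeric matrix, one column per segment.
#' @param labels character vector, one per segment; drawn from the event
#'   alphabet (`QueenPresent`, `QueenAbsent`, `NoBee`) or `"synthetic"`.
#' @param rate sampling rate (Hz) shared by all segments.
#' @param source_id character vector (recycled) naming each segment's origin.
#' @param segment_index integer vector (recycled) of each segment's position
#'   within its source recording.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, rate,
                        source_id = "", segment_index = seq_len(ncol(segments))) {
  if (!is.matrix(segments)) segments <- matrix(segments, ncol = 1L)
  n <- ncol(segments)
  labels <- as.character(rep_len(labels, n))
  structure(list(segments = segments,
                 labels = labels,
                 rate = as.numeric(rate),
                 source_id = rep_len(as.character(source_id), n),
                 segment_index = rep_len(as.integer(segment_index), n)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %d samples at %.0f Hz\n",
              ncol(x$segments), nrow(x$segments), x$rate))
  if (ncol(x$segments)) print(table(x$labels))
  invisible(x)
}

#' @export
length.segment_set <- function(x) ncol(x$segments)

#' @export
`[.segment_set` <- function(x, i) {
  segment_set(x$segments[, i, drop = FALSE], x$labels[i], x$rate,
              x$source_id[i], x$segment_index[i])
}

#' @export
c.segment_set <- function(...) {
  sets <- list(...)
  rates <- vapply(sets, function(s) s$rate, 0)
  lens <- vapply(sets, function(s) nrow(s$segments), 0L)
  if (length(unique(rates)) > 1L || length(unique(lens)) > 1L)
    stopf("cannot combine segment sets with differing rates or lengths")
  segment_set(do.call(cbind, lapply(sets, `[[`, "segments")),
              unlist(lapply(sets, `[[`, "labels")),
              rates[1],
              unlist(lapply(sets, `[[`, "source_id")),
              unlist(lapply(sets, `[[`, "segment_index")))
}

#' Extract one segment as a waveform
#' @param x a `segment_set`.
#' @param i segment index.
#' @return A [waveform].
#' @export
segment_waveform <- function(x, i) {
  waveform(x$segments[, i], x$rate, source_id = x$source_id[i],
           label = x$labels[i])
}

#' Segment manifest as a data frame
#'
#' One row per segment: `source_id`, `segment_index`, `label`, `n_samples`,
#' `rate` — the CSV schema used by [write_segment_set].
#' @param x a `segment_set`.
#' @param ... unused.
#' @return A `data.frame`.
#' @export
as.data.frame.segment_set <- function(x, ...) {
  data.frame(source_id = x$source_id,
             segment_index = x$segment_index,
             label = x$labels,
             n_samples = rep(nrow(x$segments), ncol(x$segments)),
             rate = rep(x$rate, ncol(x$segments)),
             stringsAsFactors = FALSE)
}

#' Write a segment set to a directory of WAV files plus a manifest CSV
#'
#' @param x a `segment_set`.
#' @param dir output directory (created if missing).
#' @param bits WAV bit depth passed to [write_wav].
#' @return The manifest path, invisibly.
#' @export
write_segment_set <- function(x, dir, bits = 16L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- as.data.frame(x)
  man$file <- sprintf("seg_%05d.wav", seq_len(ncol(x$segments)))
  for (i in seq_len(ncol(x$segments)))
    write_wav(segment_waveform(x, i), file.path(dir, man$file[i]), bits = bits)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a segment set written by [write_segment_set]
#'
#' @param dir directory containing `manifest.csv` and the WAV files.
#' @return A `segment_set`.
#' @export
read_segment_set <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stopf("empty manifest in '%s'", dir)
  waves <- lapply(file.path(dir, man$file), load_wav)
  segment_set(vapply(waves, function(w) w$samples, numeric(man$n_samples[1])),
              man$label, man$rate[1], man$source_id, man$segment_index)
}
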