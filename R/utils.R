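# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

#' Split a signal into (possibly partial-final-dropped) analysis frames.
#' Returns a matrix frame_len x n_frames; frames beyond the signal are not
#' emitted (no padding here).
#' @keywords internal
frame_signal <- function(x, frame_len = 1024L, hop = 512L) {
  n <- length(x)
  if (n < frame_len) return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  starts <- seq.int(1L, n - frame_len + 1L, by = hop)
  vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len))
}

#' Deterministic 32-bit FNV-1a hash of a character string, kept positive and
#' below 2^31 so it can seed R's RNG.
#' @keywords internal
hash32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    # 32-bit modular multiply by the FNV prime, done in doubles
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Derive a child seed from a master seed and stream labels
#'
#' Hashes `(seed, ...)` into a new 31-bit seed so that independent stages,
#' clips or experiment arms get reproducible, distinct RNG streams that do
#' not depend on execution order.
#'
#' @param seed master integer seed.
#' @param ... stream labels (coerced to character).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "train") != derive_seed(1, "generate")
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  hash32(key)
}

#' Evaluate an expression under a local RNG seed, restoring the caller's RNG
#' state afterwards.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' The three hive-event labels used throughout.
#' @keywords internal
EVENT_LABELS <- c("QueenPresent", "QueenAbsent", "NoBee")
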