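#' Acoustic feature configuration
#'
#' Controls the two feature maps: (a) the refinement feature vector used by
#' the Markov-chain stage — log energies in `n_bands` log-spaced bands over
#' \[`band_low`, `band_high`\] Hz plus six amplitude/spectral/temporal
#' summaries (dimension `n_bands + 6`, default 22); (b) the `mfcc_n`
#' mel-frequency cepstral coefficients (default 20) fed to the classifier.
#'
#' @param n_bands number of log-spaced band-energy bins (default 16).
#' @param band_low,band_high band-energy support in Hz (defaults 20, 2000).
#' @param frame_len,hop frame length and hop in samples for framewise
#'   statistics (defaults 1024, 512).
#' @param mfcc_n number of MFCC coefficients (default 20).
#' @param n_mels mel filters used before the cepstral transform (default 32).
#' @param floor_db log-energy floor in dB (default -80).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_bands = 16L, band_low = 20, band_high = 2000,
                           frame_len = 1024L, hop = 512L,
                           mfcc_n = 20L, n_mels = 32L, floor_db = -80) {
  stopifnot(n_bands >= 2, mfcc_n >= 1, n_mels >= mfcc_n)
  structure(list(n_bands = as.integer(n_bands), band_low = band_low,
                 band_high = band_high, frame_len = as.integer(frame_len),
                 hop = as.integer(hop), mfcc_n = as.integer(mfcc_n),
                 n_mels = as.integer(n_mels), floor_db = floor_db),
            class = "feature_config")
}

#' Refinement feature vector of one segment
#'
#' The feature-level state the Markov-chain refinement works in. For a
#' standardized segment it returns, in order: `n_bands` log band energies
#' (dB, log-spaced bins over \[`band_low`, `band_high`\], floored at
#' `floor_db`) describing the spectral energy distribution; frame-RMS mean
#' and standard deviation (amplitude variation); spectral-centroid mean and
#' standard deviation; zero-crossing rate; and the normalized
#' autocorrelation peak over 2–50 ms lags (short-term temporal structure).
#' Deterministic; scaling the audio by `g` shifts every band energy by
#' `20*log10(g)` dB and leaves centroid features unchanged.
#'
#' @param w a [waveform] (one standardized segment).
#' @param cfg a [feature_config].
#' @return Named numeric vector of length `n_bands + 6`.
#' @export
extract_refinement_features <- function(w, cfg = feature_config()) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (is.matrix(x)) stopf("expected a mono segment")
  n <- length(x)
  if (n < cfg$frame_len) stopf("segment shorter than one analysis frame")

  # --- spectral energy distribution: log-spaced band energies -------------
  spec <- Mod(stats::fft(x))[seq_len(n %/% 2L)]^2
  freqs <- (seq_len(n %/% 2L) - 1L) * w$rate / n
  edges <- exp(seq(log(cfg$band_low), log(cfg$band_high),
                   length.out = cfg$n_bands + 1L))
  band_e <- numeric(cfg$n_bands)
  for (b in seq_len(cfg$n_bands)) {
    sel <- freqs >= edges[b] & freqs < edges[b + 1L]
    band_e[b] <- sum(spec[sel])
  }
  band_db <- pmax(10 * log10(pmax(band_e, .Machine$double.xmin)), cfg$floor_db)

  # --- amplitude variation ------------------------------------------------
  fr <- frame_signal(x, cfg$frame_len, cfg$hop)
  frame_rms <- sqrt(colMeans(fr^2))

  # --- spectral centroid statistics ---------------------------------------
  cent <- spectral_centroid_frames(x, w$rate, cfg$frame_len, cfg$hop)

  # --- short-term temporal structure --------------------------------------
  zcr <- mean(abs(diff(sign(x))) > 0)
  lag_min <- max(1L, round(0.002 * w$rate))
  lag_max <- min(n - 1L, round(0.050 * w$rate))
  ac_peak <- if (stats::var(x) > 0 && lag_max >= lag_min) {
    ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
    max(ac[lag_min:lag_max])
  } else 0

  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  c(stats::setNames(band_db, sprintf("band_db_%02d", seq_len(cfg$n_bands))),
    rms_mean = mean(frame_rms), rms_sd = sd0(frame_rms),
    centroid_mean = mean(cent), centroid_sd = sd0(cent),
    zcr = zcr, ac_peak = ac_peak)
}

# Per-frame spectral centroid (Hz); all-zero frames give 0 by convention.
# Hann window: its fast sidelobe rolloff keeps far-band leakage from
# biasing the magnitude-weighted mean (a tone's centroid stays within a
# bin of the tone).
#' @keywords internal
spectral_centroid_frames <- function(x, rate, frame_len = 1024L, hop = 512L) {
  fr <- frame_signal(x, frame_len, hop)
  if (ncol(fr) == 0L) return(numeric(0))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1L) / (frame_len - 1L))
  nb <- frame_len %/% 2L
  freqs <- (seq_len(nb) - 1L) * rate / frame_len
  apply(fr, 2, function(f) {
    mag <- Mod(stats::fft(f * win))[seq_len(nb)]
    s <- sum(mag)
    if (s == 0) 0 else sum(freqs * mag) / s
  })
}

#' Feature matrix of a segment set
#'
#' Applies a per-segment feature map over a [segment_set].
#' @param x a [segment_set].
#' @param cfg a [feature_config].
#' @param type `"refinement"` (default) or `"mfcc"`.
#' @return Numeric matrix, one row per segment.
#' @export
feature_matrix <- function(x, cfg = feature_config(),
                           type = c("refinement", "mfcc")) {
  type <- match.arg(type)
  f <- switch(type, refinement = extract_refinement_features,
              mfcc = extract_mfcc)
  t(vapply(seq_len(length(x)),
           function(i) f(segment_waveform(x, i), cfg),
           numeric(if (type == "refinement") cfg$n_bands + 6L else cfg$mfcc_n)))
}

#' MFCC representation of one segment
#'
#' Standard mel-frequency cepstral coefficients: Hamming-windowed frames
#' (`frame_len`/`hop`), power spectrum, `n_mels` triangular mel filters over
#' \[0, rate/2\], log energies, orthonormal DCT-II, first `mfcc_n`
#' coefficients (including the 0th), averaged over frames into a single
#' vector per segment.
#'
#' @param w a [waveform] (one standardized segment).
#' @param cfg a [feature_config].
#' @return Numeric vector of length `mfcc_n`.
#' @export
extract_mfcc <- function(w, cfg = feature_config()) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  fr <- frame_signal(x, cfg$frame_len, cfg$hop)
  if (ncol(fr) == 0L) stopf("segment shorter than one analysis frame")
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(cfg$frame_len) - 1L) /
                             (cfg$frame_len - 1L))
  nb <- cfg$frame_len %/% 2L + 1L
  pow <- apply(fr, 2, function(f) Mod(stats::fft(f * win))[seq_len(nb)]^2)
  fb <- mel_filterbank(cfg$n_mels, cfg$frame_len, w$rate)
  loge <- log(pmax(fb %*% pow, 1e-12))
  dct <- dct_matrix(cfg$mfcc_n, cfg$n_mels)
  rowMeans(dct %*% loge)
}

#' @keywords internal
mel_filterbank <- function(n_mels, frame_len, rate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  nb <- frame_len %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * rate / frame_len
  pts <- mel2hz(seq(hz2mel(0), hz2mel(rate / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, nb)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; mid <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II, first n_keep rows.
#' @keywords internal
dct_matrix <- function(n_keep, n_in) {
  m <- outer(seq_len(n_keep) - 1L, seq_len(n_in) - 0.5,
             function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
  # note: row 0 keeps the sqrt(2/n) scale; orthonormality up to the first
  # row's constant factor is irrelevant downstream (features are z-scored)
}

#' Fit a diagonal Gaussian prior over feature space
#'
#' Sample mean and per-coordinate sample variance (population convention,
#' i.e. divisor `n`), with each variance floored at `eps` so the density is
#' strictly positive everywhere. This is the Gaussian prior `p(.)` whose
#' density ratios drive the Metropolis-Hastings acceptance rule.
#'
#' @param vectors numeric matrix, one feature vector per row (at least 2).
#' @param eps variance floor (default 1e-6).
#' @return An object of class `gaussian_prior` with fields `mean`,
#'   `variance`, `fitted_on`.
#' @export
fit_gaussian_prior <- function(vectors, eps = 1e-6) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stopf("need at least 2 vectors to fit a prior")
  mu <- colMeans(vectors)
  v <- colMeans(sweep(vectors, 2, mu)^2)      # population variance
  structure(list(mean = mu, variance = pmax(v, eps),
                 fitted_on = nrow(vectors)),
            class = "gaussian_prior")
}

#' @export
print.gaussian_prior <- function(x, ...) {
  cat(sprintf("<gaussian_prior> d = %d, fitted on %d vectors\n",
              length(x$mean), x$fitted_on))
  invisible(x)
}

#' Log density under a diagonal Gaussian prior
#'
#' Unnormalized-safe: the additive constant is included, but only density
#' ratios (log differences) enter the acceptance rule, so any constant
#' offset cancels.
#'
#' @param prior a [fit_gaussian_prior] result.
#' @param x numeric vector (or matrix, one vector per row).
#' @return Log density value(s).
#' @export
prior_logpdf <- function(prior, x) {
  stopifnot(inherits(prior, "gaussian_prior"))
  if (is.matrix(x)) {
    z <- sweep(sweep(x, 2, prior$mean), 2, sqrt(prior$variance), "/")
    -0.5 * rowSums(z^2) - 0.5 * sum(log(2 * pi * prior$variance))
  } else {
    if (length(x) != length(prior$mean)) stopf("dimension mismatch")
    z <- (x - prior$mean) / sqrt(prior$variance)
    -0.5 * sum(z^2) - 0.5 * sum(log(2 * pi * prior$variance))
  }
}

#' Transition vectors from randomly paired real feature rows
#'
#' Draws a seeded random permutation and differences consecutive rows,
#' giving `n - 1` feature-space transitions; the default support on which
#' the Gaussian prior is fitted (`prior_on = "transitions"`).
#'
#' @param features numeric matrix, one feature vector per row.
#' @param seed integer seed for the pairing.
#' @return Matrix of `nrow(features) - 1` transition vectors.
#' @export
transition_sample <- function(features, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stopf("need at least 2 feature vectors")
  perm <- with_seed(derive_seed(seed, "transitions"), sample.int(n))
  diff(features[perm, , drop = FALSE])
}
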