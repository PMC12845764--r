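#' Distribution summaries of audio characteristics
#'
#' A `dist_summary` is a normalized histogram (masses sum to 1) over a
#' stated support, for one of the three diagnostic kinds: spectral
#' `"frequency"` mass, sample `"amplitude"`, or per-frame spectral
#' `"centroid"`.
#'
#' @param masses non-negative bin masses.
#' @param edges strictly increasing bin edges (length `length(masses)+1`).
#' @param kind one of `"frequency"`, `"amplitude"`, `"centroid"`.
#' @return An object of class `dist_summary`.
#' @export
dist_summary <- function(masses, edges, kind) {
  if (any(masses < 0)) stopf("histogram masses must be non-negative")
  if (any(diff(edges) <= 0)) stopf("bin edges must be strictly increasing")
  if (length(edges) != length(masses) + 1L) stopf("edges/masses length mismatch")
  s <- sum(masses)
  if (s > 0) masses <- masses / s
  structure(list(masses = masses, edges = edges, kind = kind),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("<dist_summary> %s, %d bins over [%.3g, %.3g]\n",
              x$kind, length(x$masses), x$edges[1],
              x$edges[length(x$edges)]))
  invisible(x)
}

#' @keywords internal
hist_masses <- function(values, weights, edges) {
  bins <- findInterval(values, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  m <- numeric(length(edges) - 1L)
  agg <- tapply(weights, bins, sum)
  m[as.integer(names(agg))] <- agg
  m
}

#' Normalized frequency distribution of a segment
#'
#' Magnitude-spectrum mass per frequency bin over \[0, rate/2\],
#' normalized to sum to 1.
#'
#' @param w a [waveform] (or a [segment_set], whose per-segment histograms
#'   are averaged).
#' @param n_bins number of bins (default 50).
#' @return A [dist_summary] of kind `"frequency"`.
#' @export
frequency_distribution <- function(w, n_bins = 50L) {
  if (inherits(w, "segment_set"))
    return(pooled_dist(w, frequency_distribution, n_bins = n_bins))
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  nb <- n %/% 2L
  mag <- Mod(stats::fft(w$samples))[seq_len(nb)]
  freqs <- (seq_len(nb) - 1L) * w$rate / n
  edges <- seq(0, w$rate / 2, length.out = n_bins + 1L)
  m <- hist_masses(freqs, mag, edges)
  if (sum(m) == 0) m <- rep(1 / n_bins, n_bins)   # all-zero clip: flat
  dist_summary(m, edges, "frequency")
}

#' Amplitude distribution of a segment
#'
#' Histogram of sample amplitudes over \[-1, 1\], normalized.
#'
#' @inheritParams frequency_distribution
#' @return A [dist_summary] of kind `"amplitude"`.
#' @export
amplitude_distribution <- function(w, n_bins = 50L) {
  if (inherits(w, "segment_set"))
    return(pooled_dist(w, amplitude_distribution, n_bins = n_bins))
  stopifnot(inherits(w, "waveform"))
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  x <- pmax(-1, pmin(1, w$samples))
  dist_summary(hist_masses(x, rep(1, length(x)), edges), edges, "amplitude")
}

#' Spectral-centroid series and distribution of a segment
#'
#' Per-frame spectral centroid (frame 1024, hop 512;
#' `sum(f |X(f)|) / sum(|X(f)|)`, all-zero frames giving 0 by convention)
#' plus its histogram over a stated support.
#'
#' @param w a [waveform].
#' @param n_bins number of bins (default 50).
#' @param edges optional shared bin edges; defaults to \[0, rate/2\].
#' @param frame_len,hop centroid frame parameters.
#' @return List with `series` (per-frame centroids, Hz) and `dist` (a
#'   [dist_summary] of kind `"centroid"`).
#' @export
spectral_centroid <- function(w, n_bins = 50L, edges = NULL,
                              frame_len = 1024L, hop = 512L) {
  stopifnot(inherits(w, "waveform"))
  cent <- spectral_centroid_frames(w$samples, w$rate, frame_len, hop)
  if (is.null(edges)) edges <- seq(0, w$rate / 2, length.out = n_bins + 1L)
  m <- hist_masses(cent, rep(1, length(cent)), edges)
  list(series = cent, dist = dist_summary(m, edges, "centroid"))
}

# Average per-segment histograms over a set (itself a valid distribution).
#' @keywords internal
pooled_dist <- function(set, f, ...) {
  ds <- lapply(seq_len(length(set)),
               function(i) f(segment_waveform(set, i), ...))
  out <- ds[[1]]
  out$masses <- rowMeans(vapply(ds, `[[`, ds[[1]]$masses, "masses"))
  out
}

#' @keywords internal
pooled_centroid_dist <- function(set, edges, frame_len = 1024L, hop = 512L) {
  cents <- unlist(lapply(seq_len(length(set)), function(i)
    spectral_centroid_frames(set$segments[, i], set$rate, frame_len, hop)))
  dist_summary(hist_masses(cents, rep(1, length(cents)), edges), edges,
               "centroid")
}

#' Jensen-Shannon divergence between two distribution summaries
#'
#' Natural-log Jensen-Shannon divergence: symmetric, non-negative, zero
#' iff the histograms coincide, bounded by `log(2)`. Requires identical
#' supports.
#'
#' @param a,b [dist_summary] objects on the same bin edges.
#' @return The divergence (a scalar in \[0, log 2\]).
#' @export
js_divergence <- function(a, b) {
  stopifnot(inherits(a, "dist_summary"), inherits(b, "dist_summary"))
  if (!isTRUE(all.equal(a$edges, b$edges)))
    stopf("js_divergence: distributions have different supports")
  p <- a$masses; q <- b$masses
  m <- (p + q) / 2
  kl <- function(x, y) {
    sel <- x > 0
    sum(x[sel] * log(x[sel] / y[sel]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Compare real, raw-GAN and refined audio distributions
#'
#' For the pooled sets and for `n_pairs` randomly sampled segment triads,
#' computes the frequency, amplitude and spectral-centroid distributions
#' of each set and the Jensen-Shannon divergences `js(real, gan)` and
#' `js(real, refined)` per kind, flagging whether refinement brought each
#' characteristic closer to the real distribution.
#'
#' @param real_set,gan_set,refined_set [segment_set]s at a common rate.
#' @param n_pairs sampled triads reported individually (default 3).
#' @param n_bins histogram bins (default 50).
#' @param seed sampling seed for the triads.
#' @param frame_len,hop centroid frame parameters; must not exceed the
#'   segment length.
#' @return An object of class `compare_report`: `pooled` (per-kind list
#'   with the three [dist_summary]s, `js_gan`, `js_refined`, `improved`),
#'   `pairs` (data.frame of per-triad divergences), `improved_all`.
#' @export
compare_report <- function(real_set, gan_set, refined_set, n_pairs = 3L,
                           n_bins = 50L, seed = 1L,
                           frame_len = 1024L, hop = 512L) {
  sets <- list(real = real_set, gan = gan_set, refined = refined_set)
  stopifnot(all(vapply(sets, inherits, TRUE, "segment_set")),
            all(vapply(sets, length, 0L) > 0L))
  rate <- real_set$rate
  if (frame_len > nrow(real_set$segments))
    stopf("centroid frame_len %d exceeds the segment length %d",
          frame_len, nrow(real_set$segments))

  # shared centroid support from the pooled data
  all_cent <- unlist(lapply(sets, function(s)
    lapply(seq_len(length(s)), function(i)
      spectral_centroid_frames(s$segments[, i], rate, frame_len, hop))))
  cent_edges <- seq(min(all_cent), max(all_cent) + 1e-9,
                    length.out = n_bins + 1L)

  pooled <- list()
  for (kind in c("frequency", "amplitude", "centroid")) {
    ds <- lapply(sets, function(s) switch(kind,
      frequency = frequency_distribution(s, n_bins),
      amplitude = amplitude_distribution(s, n_bins),
      centroid = pooled_centroid_dist(s, cent_edges, frame_len, hop)))
    jg <- js_divergence(ds$real, ds$gan)
    jr <- js_divergence(ds$real, ds$refined)
    pooled[[kind]] <- list(real = ds$real, gan = ds$gan,
                           refined = ds$refined, js_gan = jg,
                           js_refined = jr, improved = jr <= jg)
  }

  pairs <- with_seed(derive_seed(seed, "triads"), {
    do.call(rbind, lapply(seq_len(n_pairs), function(p) {
      idx <- vapply(sets, function(s) sample.int(length(s), 1L), 0L)
      do.call(rbind, lapply(c("frequency", "amplitude"), function(kind) {
        f <- if (kind == "frequency") frequency_distribution
             else amplitude_distribution
        dr <- f(segment_waveform(sets$real, idx[1]), n_bins)
        dg <- f(segment_waveform(sets$gan, idx[2]), n_bins)
        dm <- f(segment_waveform(sets$refined, idx[3]), n_bins)
        data.frame(pair = p, kind = kind,
                   js_gan = js_divergence(dr, dg),
                   js_refined = js_divergence(dr, dm))
      }))
    }))
  })

  structure(list(pooled = pooled, pairs = pairs,
                 improved_all = all(vapply(pooled, `[[`, TRUE, "improved"))),
            class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat("<compare_report> pooled Jensen-Shannon divergences vs real:\n")
  for (kind in names(x$pooled)) {
    p <- x$pooled[[kind]]
    cat(sprintf("  %-9s gan %.4f  refined %.4f  %s\n", kind, p$js_gan,
                p$js_refined, if (p$improved) "(improved)" else ""))
  }
  invisible(x)
}

#' LDA-plane projection of real and synthetic sets
#'
#' Projects every segment of each named set through the reference
#' classifier's standardization and LDA map to the 2-D discriminant plane,
#' and summarizes each set by its centroid and mean within-set dispersion
#' (mean Euclidean distance to the centroid).
#'
#' @param model a fitted [lda_svm] (3 classes give a 2-D plane).
#' @param sets a named list of [segment_set]s.
#' @return List: `coords` (data.frame: set, label, one column per
#'   discriminant), `summary` (per-set centroid and dispersion).
#' @export
lda_projection <- function(model, sets) {
  stopifnot(inherits(model, "lda_svm"), is.list(sets),
            !is.null(names(sets)))
  coords <- do.call(rbind, lapply(names(sets), function(nm) {
    xy <- lda_project(model, sets[[nm]])
    data.frame(set = nm, label = sets[[nm]]$labels,
               LD1 = xy[, 1], LD2 = if (ncol(xy) > 1) xy[, 2] else 0,
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(names(sets), function(nm) {
    xy <- coords[coords$set == nm, c("LD1", "LD2")]
    ctr <- colMeans(xy)
    data.frame(set = nm, LD1 = ctr[1], LD2 = ctr[2],
               dispersion = mean(sqrt(rowSums(sweep(as.matrix(xy), 2,
                                                    ctr)^2))),
               stringsAsFactors = FALSE)
  }))
  list(coords = coords, summary = summary)
}
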