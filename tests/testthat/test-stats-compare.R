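test_that("frequency distributions are normalized and concentrate on tones", {
  w <- sine_wave(500, rate = 8192)
  d <- frequency_distribution(w)
  expect_s3_class(d, "dist_summary")
  expect_equal(sum(d$masses), 1, tolerance = 1e-9)
  bin500 <- findInterval(500, d$edges)
  expect_gte(d$masses[bin500], 0.9)

  # white noise stays near-flat over seeded draws
  for (s in 1:20) {
    n <- withr::with_seed(s, waveform(rnorm(4096, 0, 0.2), 8192))
    dn <- frequency_distribution(n)
    expect_lt(max(dn$masses), 3 / length(dn$masses))
  }
})

test_that("amplitude distributions cover [-1, 1] and respect symmetry", {
  const <- waveform(rep(0.5, 2048), 8192)
  d <- amplitude_distribution(const)
  expect_equal(sum(d$masses), 1, tolerance = 1e-9)
  expect_equal(max(d$masses), 1)
  expect_equal(findInterval(0.5, d$edges), which.max(d$masses))

  s <- amplitude_distribution(sine_wave(100, rate = 8192))
  flipped <- rev(s$masses)
  expect_true(all(abs(s$masses - flipped) < 0.02))
})

test_that("spectral centroids track tones and order noise by bandwidth", {
  tone <- sine_wave(500, rate = 8192)
  sc <- spectral_centroid(tone)
  bin_w <- 8192 / 1024
  expect_lt(abs(mean(sc$series) - 500), bin_w + 1e-9)
  expect_equal(sum(sc$dist$masses), 1, tolerance = 1e-9)

  z <- waveform(rep(0, 2048), 8192)
  expect_true(all(spectral_centroid(z)$series == 0))

  white <- withr::with_seed(3, waveform(rnorm(8192), 8192))
  lp <- bandpass(waveform(white$samples, 8192),
                 preprocess_config(target_rate = 8192, band_low = 20,
                                   band_high = 800, segment_len = 1024))
  expect_lt(mean(spectral_centroid(lp)$series),
            mean(spectral_centroid(white)$series))
})

test_that("Jensen-Shannon divergence is a bounded symmetric divergence", {
  e <- seq(0, 1, length.out = 11)
  a <- dist_summary(rep(1, 10), e, "amplitude")
  expect_equal(js_divergence(a, a), 0)

  left <- dist_summary(c(1, rep(0, 9)), e, "amplitude")
  right <- dist_summary(c(rep(0, 9), 1), e, "amplitude")
  expect_equal(js_divergence(left, right), log(2), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    p <- dist_summary(runif(10), e, "amplitude")
    q <- dist_summary(runif(10), e, "amplitude")
    d1 <- js_divergence(p, q)
    expect_equal(d1, js_divergence(q, p))
    expect_gte(d1, 0); expect_lte(d1, log(2) + 1e-12)
  }
  b <- dist_summary(rep(1, 10), seq(0, 2, length.out = 11), "amplitude")
  expect_error(js_divergence(a, b), "support")
})

test_that("compare reports flag refinement gains and keep their shape", {
  segs <- tiny_segs()
  real <- segs[segs$labels == "QueenPresent"][1:30]
  gan <- segs[segs$labels == "NoBee"][1:30]
  rep1 <- compare_report(real, gan, real, n_pairs = 2, seed = 1)
  expect_named(rep1$pooled, c("frequency", "amplitude", "centroid"))
  for (kind in names(rep1$pooled)) {
    expect_equal(rep1$pooled[[kind]]$js_refined, 0, tolerance = 1e-12)
    expect_true(rep1$pooled[[kind]]$improved)
  }
  expect_true(rep1$improved_all)
  expect_equal(nrow(rep1$pairs), 2 * 2)     # 2 triads x 2 per-pair kinds
})

test_that("refinement toward real fixtures improves the distribution flags", {
  # fixture experiment mirroring a partly-correct generated pool: half the
  # pool resembles the real class, half is heavily distorted; refinement
  # should over-select the realistic half, moving every pooled histogram
  # toward the real one
  wins <- 0L
  for (s in 1:20) {
    real <- tiny_segs()[tiny_segs()$labels == "QueenPresent"]
    good <- tiny_segs(2, seed = 100 + s)
    good <- good[good$labels == "QueenPresent"]
    bad <- good
    bad$segments <- 0.15 * bad$segments +
      withr::with_seed(s, matrix(rnorm(length(bad$segments), 0, 0.02),
                                 nrow(bad$segments)))
    pool <- c(good, bad)
    cfg <- refine_config(beta = 0.9, n_out = 40, seed = s)
    rs <- suppressWarnings(refine(pool, real, cfg, tiny_fc()))
    if (length(rs$indices) < 10) next
    cr <- compare_report(real, pool, rs$clips, n_pairs = 2, seed = s)
    if (cr$improved_all) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("LDA projections are 2-D with distinct class centroids", {
  segs <- tiny_segs()
  m <- tiny_ref()
  sets <- list(qp = segs[segs$labels == "QueenPresent"][1:20],
               nb = segs[segs$labels == "NoBee"][1:20])
  proj <- lda_projection(m, sets)
  expect_equal(nrow(proj$coords), 40L)
  expect_true(all(c("LD1", "LD2") %in% names(proj$coords)))
  ctrs <- proj$summary
  d <- sqrt((ctrs$LD1[1] - ctrs$LD1[2])^2 + (ctrs$LD2[1] - ctrs$LD2[2])^2)
  expect_gt(d, 1)
  expect_true(all(ctrs$dispersion >= 0))
})
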