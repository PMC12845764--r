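test_that("the transition vector obeys its limiting and arithmetic identities", {
  v <- c(1, 0); s <- c(0, 0); r <- c(2, 2)
  expect_identical(transition_vector(v, s, r, 0), v - s)
  expect_identical(transition_vector(v, s, r, 1), v - r)
  expect_equal(transition_vector(v, s, r, 0.5), c(0, -1))
  set.seed(2)
  for (i in 1:20) {
    b <- runif(1); vv <- rnorm(4); ss <- rnorm(4); rr <- rnorm(4)
    expect_equal(transition_vector(vv, ss, rr, b),
                 (1 - b) * (vv - ss) + b * (vv - rr))
  }
  expect_error(transition_vector(c(1, 2), c(1, 2, 3), c(0, 0), 0.5),
               "dimension")
  expect_error(transition_vector(v, s, r, 1.2), "beta")
})

test_that("the acceptance probability is a clipped Gaussian density ratio", {
  p1 <- fit_gaussian_prior(rbind(-1, 1))     # 1-D, mean 0, variance 1
  expect_equal(p1$mean, 0, ignore_attr = TRUE)
  expect_equal(p1$variance, 1, ignore_attr = TRUE)
  expect_equal(acceptance_probability(1, 0, p1), exp(-0.5))
  expect_equal(acceptance_probability(0, 1, p1), 1)   # clipped at 1
  expect_equal(acceptance_probability(0.3, 0.3, p1), 1)

  set.seed(4)
  prior <- fit_gaussian_prior(matrix(rnorm(60), ncol = 3))
  for (i in 1:50) {
    a <- acceptance_probability(rnorm(3, sd = 3), rnorm(3, sd = 3), prior)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("EMA smoothing interpolates and converges to a constant stream", {
  expect_equal(ema_smooth(0, 10, 0.2), 2)
  expect_equal(ema_smooth(c(1, 2), c(3, 4), 1), c(3, 4))
  expect_equal(ema_smooth(NULL, c(7, 7), 0.2), c(7, 7))
  acc <- NULL
  for (i in 1:60) acc <- ema_smooth(acc, c(4, -2), 0.3)
  expect_equal(acc, c(4, -2), tolerance = 1e-8)
})

test_that("mh_step accepts on unit ratio and stands still when u >= alpha", {
  cfg <- refine_config(beta = 1, n_out = 5, seed = 1)
  # all pool and real features identical: every proposal equals the state,
  # the ratio is 1, acceptance is certain
  pool <- matrix(1, 10, 3); real <- matrix(0, 10, 3)
  prior <- fit_gaussian_prior(rbind(c(0.9, 0.9, 0.9), c(1.1, 1.1, 1.1)))
  set.seed(3)
  st <- chain_init(pool, real, cfg$beta)
  for (i in 1:20) st <- mh_step(st, pool, real, prior, cfg)
  expect_equal(st$n_accept, 20L)
  expect_equal(st$t, 20L)

  # a state vastly more probable than any proposal: nothing is accepted
  prior0 <- fit_gaussian_prior(rbind(c(-0.01, 0, 0), c(0.01, 0, 0)))
  st2 <- structure(list(theta = c(0, 0, 0), s = pool[1, ], ema = NULL,
                        accepted_idx = integer(0), accepted_feat = list(),
                        t = 0L, n_accept = 0L), class = "chain_state")
  set.seed(3)
  for (i in 1:50) st2 <- mh_step(st2, pool, real, prior0, cfg)
  expect_equal(st2$n_accept, 0L)
  expect_equal(st2$t, 50L)
  expect_equal(st2$theta, c(0, 0, 0))
})

test_that("refinement reaches n_out on matched pools and reruns identically", {
  set.seed(8)
  feats <- matrix(rnorm(200 * 4), ncol = 4)
  cfg <- refine_config(beta = 0.5, n_out = 50, seed = 13)
  r1 <- refine_features(feats, feats, cfg)
  expect_equal(nrow(r1$features), 50L)
  expect_length(r1$indices, 50L)
  expect_gte(r1$acceptance_rate, 0.5)
  r2 <- refine_features(feats, feats, cfg)
  expect_identical(r1$indices, r2$indices)

  # budget exhaustion warns and returns a partial set
  near <- matrix(rnorm(50 * 4, sd = 1e-4), ncol = 4)
  far <- sweep(matrix(rnorm(50 * 4, sd = 1e-4), ncol = 4), 2, 100, "+")
  cfg2 <- refine_config(beta = 1, n_out = 30, max_iters = 50, seed = 2)
  expect_warning(rp <- refine_features(far, near, cfg2), "budget")
  expect_lt(length(rp$indices), 30)
})

test_that("audio refinement emits pool clips relabeled to the real class", {
  pool <- tiny_segs()[tiny_segs()$labels == "NoBee"][1:40]
  reals <- tiny_segs()[tiny_segs()$labels == "QueenPresent"][1:40]
  cfg <- refine_config(beta = 0.1, n_out = 5, seed = 3)
  rs <- suppressWarnings(refine(pool, reals, cfg, tiny_fc()))
  expect_s3_class(rs, "refined_set")
  for (k in seq_along(rs$indices))
    expect_identical(rs$clips$segments[, k],
                     pool$segments[, rs$indices[k]])
  expect_true(all(rs$clips$labels == "QueenPresent"))
})

test_that("EMA smoothing reduces roughness of the accepted feature path", {
  set.seed(10)
  feats <- matrix(rnorm(300 * 4), ncol = 4)
  cfg <- refine_config(beta = 0.5, n_out = 80, ema_alpha = 0.3, seed = 4)
  res <- refine_features(feats, feats, cfg)
  raw <- feats[res$indices, ]
  mssd <- function(m) mean(rowSums(diff(m)^2))
  expect_lte(mssd(res$features), mssd(raw))
})

test_that("beta sweeps tabulate counts per class and flag the best beta", {
  pool <- tiny_segs()[tiny_segs()$labels == "QueenPresent"][1:60]
  reals <- tiny_segs()[tiny_segs()$labels == "QueenPresent"][61:80]
  cfg <- refine_config(beta = 0.5, n_out = 20, seed = 5)
  sw <- suppressWarnings(
    sweep_beta(pool, reals, c(0.1, 0.9), cfg, tiny_ref(),
               feature_cfg = tiny_fc()))
  expect_equal(nrow(sw$table), 2L)
  expect_true(all(c("QueenPresent", "QueenAbsent", "NoBee") %in%
                    names(sw$table)))
  counts <- rowSums(sw$table[, c("QueenPresent", "QueenAbsent", "NoBee")])
  expect_true(all(counts <= 20))
  expect_true(sw$beta_opt %in% c(0.1, 0.9))

  one <- suppressWarnings(
    sweep_beta(pool, reals, 0.3, cfg, tiny_ref(), feature_cfg = tiny_fc()))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$beta_opt, 0.3)
})
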