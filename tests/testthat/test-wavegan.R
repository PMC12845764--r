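test_that("generator obeys its shape, bound and determinism contracts", {
  cfg <- tiny_gan_cfg()
  g <- build_generator(cfg, seed = 4)
  z <- matrix(runif(cfg$latent_dim * 3, -1, 1), cfg$latent_dim)
  y <- g(z)
  expect_equal(dim(y), c(1024L, 3L))
  expect_true(all(abs(y) <= 1))
  expect_identical(g(z), y)
  expect_error(gan_config(output_len = 1000), "stride")
})

test_that("critic scores are finite, and deterministic without phase shuffle", {
  cfg0 <- tiny_gan_cfg(phase_shuffle_n = 0)
  d0 <- build_discriminator(cfg0, seed = 4)
  x <- matrix(rnorm(1024 * 4, 0, 0.3), 1024)
  s <- d0(x)
  expect_length(s, 4L)
  expect_true(all(is.finite(s)))
  expect_identical(d0(x), s)

  cfg2 <- tiny_gan_cfg(phase_shuffle_n = 2)
  d2 <- build_discriminator(cfg2, seed = 4)
  s1 <- withr::with_seed(9, d2(x))
  s2 <- withr::with_seed(9, d2(x))
  expect_identical(s1, s2)
  expect_error(d2(matrix(0, 500, 2)), "expects clips")
})

test_that("gradient penalty matches its closed forms", {
  L <- 64L
  real <- matrix(rnorm(L * 4), L); fake <- matrix(rnorm(L * 4), L)
  # critic(x) = sum(x): gradient is all-ones, norm sqrt(L)
  gp <- gradient_penalty(colSums, real, fake, gp_lambda = 10,
                         grad_fn = function(x) matrix(1, nrow(x), ncol(x)))
  expect_equal(gp, 10 * (sqrt(L) - 1)^2, tolerance = 1e-12)
  # constant critic: zero gradient, penalty = lambda
  gp0 <- gradient_penalty(function(x) rep(3, ncol(x)), real, fake,
                          gp_lambda = 10)
  expect_equal(gp0, 10, tolerance = 1e-6)
  expect_identical(gradient_penalty(colSums, real, fake, gp_lambda = 0), 0)
})

test_that("backpropagated penalty gradients match the finite-difference oracle", {
  cfg <- tiny_gan_cfg(phase_shuffle_n = 0)
  d <- build_discriminator(cfg, seed = 8)
  real <- matrix(rnorm(1024 * 2, 0, 0.2), 1024)
  fake <- matrix(rnorm(1024 * 2, 0, 0.2), 1024)
  exact <- gradient_penalty(d, real, fake, gp_lambda = 10, seed = 3)
  fd <- gradient_penalty(unclass(d), real, fake, gp_lambda = 10, seed = 3,
                         fd_step = 1e-5)
  expect_equal(exact, fd, tolerance = 1e-3)
})

test_that("training checkpoints, reruns deterministically, and generates", {
  qp <- tiny_segs()[tiny_segs()$labels == "QueenPresent"]
  m <- tiny_gan()
  expect_s3_class(m, "wavegan")
  expect_length(m$checkpoints, 2L)           # 10 iterations / every 5
  expect_equal(vapply(m$checkpoints, `[[`, 0L, "iteration"), c(5L, 10L))
  expect_true(all(is.finite(as.matrix(m$trace[-1]))))
  expect_equal(dim(m$checkpoints[[1]]$samples),
               c(1024L, m$cfg$checkpoint_samples))

  m2 <- wavegan_train(qp, tiny_gan_cfg(seed = 11, iterations = 10))
  expect_identical(m2$trace, m$trace)

  g64 <- wavegan_generate(m, 64, seed = 5)
  expect_equal(length(g64), 64L)
  expect_true(all(g64$labels == "synthetic"))
  expect_identical(wavegan_generate(m, 64, seed = 5)$segments, g64$segments)
  g1 <- wavegan_generate(m, 1, seed = 2)
  expect_true(all(abs(g1$segments) <= 1))
  expect_error(wavegan_train(tiny_segs()[integer(0)], tiny_gan_cfg()),
               "empty")
})

test_that("checkpoint selection maximizes the target count, earliest on ties", {
  segs <- tiny_segs()
  ref <- tiny_ref()
  qp <- segs$segments[, segs$labels == "QueenPresent"][, 1:10]
  nb <- segs$segments[, segs$labels == "NoBee"][, 1:10]
  fake_model <- structure(list(
    cfg = tiny_gan_cfg(),
    rate = segs$rate,
    checkpoints = list(
      list(iteration = 5L, params = NULL, samples = nb),
      list(iteration = 10L, params = NULL, samples = qp),
      list(iteration = 15L, params = NULL,
           samples = cbind(qp[, 1:5], nb[, 1:5])))),
    class = "wavegan")
  sel <- select_converged(fake_model, ref, "QueenPresent")
  expect_equal(sel$iteration, 10L)
  expect_equal(sel$counts[2], max(sel$counts))

  tied <- fake_model
  tied$checkpoints <- fake_model$checkpoints[c(2, 2)]
  tied$checkpoints[[2]]$iteration <- 20L
  expect_equal(select_converged(tied, ref, "QueenPresent")$iteration, 10L)

  single <- fake_model; single$checkpoints <- fake_model$checkpoints[2]
  expect_equal(select_converged(single, ref, "QueenPresent")$iteration, 10L)
  empty <- fake_model; empty$checkpoints <- list()
  expect_error(select_converged(empty, ref, "QueenPresent"), "empty")
})
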