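# The conv stack is the package's own numerical core, so it is checked
# against an independent direct-convolution oracle and finite differences.

naive_conv1d <- function(x, W, b, stride, pad) {
  L <- dim(x)[1]; Ci <- dim(x)[2]; B <- dim(x)[3]
  K <- dim(W)[1]; Co <- dim(W)[3]
  Lo <- (L + 2 * pad - K) %/% stride + 1
  y <- array(0, c(Lo, Co, B))
  for (bb in 1:B) for (co in 1:Co) for (lo in 1:Lo) {
    acc <- b[co]
    for (ci in 1:Ci) for (k in 1:K) {
      i <- (lo - 1) * stride + k - pad
      if (i >= 1 && i <= L) acc <- acc + x[i, ci, bb] * W[k, ci, co]
    }
    y[lo, co, bb] <- acc
  }
  y
}

test_that("GEMM convolution matches a direct convolution oracle", {
  set.seed(5)
  x <- array(rnorm(32 * 2 * 3), c(32, 2, 3))
  W <- array(rnorm(5 * 2 * 4), c(5, 2, 4))
  b <- rnorm(4)
  got <- mcwavegan:::nn_conv_fwd(x, W, b, stride = 4L, pad = 2L)
  want <- naive_conv1d(x, W, b, stride = 4L, pad = 2L)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  set.seed(6)
  W <- array(rnorm(25 * 3 * 2), c(25, 3, 2))     # (K, Ci, Co)
  x <- array(rnorm(64 * 3 * 2), c(64, 3, 2))
  y <- array(rnorm(16 * 2 * 2), c(16, 2, 2))
  Ax <- mcwavegan:::nn_conv_fwd(x, W, numeric(2), stride = 4L, pad = 12L)
  Aty <- mcwavegan:::nn_conv_bwd_input(y, W, L = 64L, stride = 4L, pad = 12L)
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-10)
})

test_that("critic and generator gradients agree with central differences", {
  cfg <- gan_config(latent_dim = 8, model_size = 2, output_len = 1024,
                    batch_size = 3, phase_shuffle_n = 0)
  ns <- asNamespace("mcwavegan")
  h <- 1e-5

  set.seed(31)
  cp <- ns$gan_init_critic(cfg, 1)
  cp <- lapply(cp, function(p) p + rnorm(length(p), 0, 0.2))
  x <- array(rnorm(1024 * 3, 0, 0.3), c(1024, 1, 3))
  gs <- c(0.3, -0.2, 0.5)
  closs <- function(p) sum(ns$gan_critic_fwd(p, cfg, x, NULL) * gs)
  fwd <- ns$gan_critic_fwd(cp, cfg, x, NULL, cache = TRUE)
  bwd <- ns$gan_critic_bwd(cp, cfg, fwd, gs, need_input_grad = TRUE)
  for (nm in names(cp)) {
    i <- sample(length(cp[[nm]]), 1)
    pp <- cp; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- cp; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (closs(pp) - closs(pm)) / (2 * h)
    expect_equal(bwd$grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("critic grad", nm))
  }
  i <- 511
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  fd <- (sum(ns$gan_critic_fwd(cp, cfg, xp, NULL) * gs) -
           sum(ns$gan_critic_fwd(cp, cfg, xm, NULL) * gs)) / (2 * h)
  expect_equal(bwd$gx[i], fd, tolerance = 1e-4)

  gp <- ns$gan_init_generator(cfg, 1)
  gp <- lapply(gp, function(p) p + rnorm(length(p), 0, 0.2))
  z <- matrix(runif(8 * 3, -1, 1), 8)
  gy <- array(rnorm(1024 * 3), c(1024, 1, 3))
  gloss <- function(p) sum(ns$gan_generator_fwd(p, cfg, z) * gy)
  fwdg <- ns$gan_generator_fwd(gp, cfg, z, cache = TRUE)
  grads <- ns$gan_generator_bwd(gp, cfg, fwdg, gy)
  for (nm in names(gp)) {
    i <- sample(length(gp[[nm]]), 1)
    pp <- gp; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- gp; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (gloss(pp) - gloss(pm)) / (2 * h)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("generator grad", nm))
  }
})

test_that("phase shuffle circularly shifts per sample and inverts", {
  ns <- asNamespace("mcwavegan")
  x <- array(seq_len(8 * 2 * 2), c(8, 2, 2))
  y <- ns$nn_phase_shift(x, c(2L, 0L))
  expect_equal(y[, 1, 1], c(7, 8, 1, 2, 3, 4, 5, 6))
  expect_equal(y[, , 2], x[, , 2])
  back <- ns$nn_phase_shift(y, c(-2L, 0L))
  expect_equal(back, x)
})
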