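#' WaveGAN configuration
#'
#' Architecture and training settings for the raw-waveform GAN. The
#' generator maps a latent vector through a dense layer and a stack of
#' stride-4 transposed convolutions (kernel 25) to a `tanh`-bounded
#' waveform; the critic mirrors it with strided convolutions, LeakyReLU and
#' phase shuffle, and is trained as a Wasserstein GAN with gradient penalty.
#' `output_len` must be `16 * 4^k` (16384 gives one-second clips at
#' 16384 Hz; 4096 and 1024 give cheaper desk-scale models).
#'
#' @param latent_dim latent dimension (default 100).
#' @param model_size channel-width multiplier (64 at full scale; the desk
#'   preset uses 16).
#' @param output_len output waveform length in samples.
#' @param kernel_len convolution kernel taps (default 25).
#' @param stride up/down-sampling factor per layer (default 4).
#' @param phase_shuffle_n maximum phase-shuffle shift in samples (default 2;
#'   0 disables it and makes the critic deterministic).
#' @param n_critic critic updates per generator update (default 5).
#' @param gp_lambda gradient-penalty weight (default 10).
#' @param batch_size minibatch size (default 64).
#' @param iterations generator iterations (120000 at full scale; the desk
#'   preset uses 2000).
#' @param checkpoint_every iterations between checkpoints (default 1000).
#' @param checkpoint_samples clips stored per checkpoint (default 64).
#' @param adam_lr,adam_beta1,adam_beta2 Adam hyperparameters
#'   (defaults 1e-4, 0.5, 0.9 — the usual WGAN-GP settings).
#' @param seed training seed.
#' @param preset `"desk"` (small CPU-scale model) or `"full"` (the full-scale configuration); fills the scale-dependent fields
#'   above, which explicit arguments still override.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 100L, model_size = NULL, output_len = NULL,
                       kernel_len = 25L, stride = 4L, phase_shuffle_n = 2L,
                       n_critic = 5L, gp_lambda = 10, batch_size = 64L,
                       iterations = NULL, checkpoint_every = 1000L,
                       checkpoint_samples = 64L,
                       adam_lr = 1e-4, adam_beta1 = 0.5, adam_beta2 = 0.9,
                       seed = 1L, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (is.null(model_size)) model_size <- if (preset == "full") 64L else 16L
  if (is.null(output_len)) output_len <- if (preset == "full") 16384L else 4096L
  if (is.null(iterations)) iterations <- if (preset == "full") 120000L else 2000L
  n_layers <- round(log(output_len / 16) / log(stride))
  if (16 * stride^n_layers != output_len || n_layers < 1)
    stopf("output_len must be 16 * stride^k for integer k >= 1 (got %d)",
          output_len)
  if (batch_size < 2) stopf("batch_size must be at least 2")
  stopifnot(latent_dim >= 1, model_size >= 1, iterations >= 1,
            checkpoint_every >= 1, n_critic >= 1, gp_lambda >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 model_size = as.integer(model_size),
                 output_len = as.integer(output_len),
                 kernel_len = as.integer(kernel_len),
                 stride = as.integer(stride),
                 n_layers = as.integer(n_layers),
                 phase_shuffle_n = as.integer(phase_shuffle_n),
                 n_critic = as.integer(n_critic), gp_lambda = gp_lambda,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_samples = as.integer(checkpoint_samples),
                 adam_lr = adam_lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, seed = as.integer(seed),
                 preset = preset),
            class = "gan_config")
}

#' Build a WaveGAN generator
#'
#' Returns a callable generator: given a `latent_dim x B` matrix (or single
#' latent vector) of codes, it produces an `output_len x B` matrix of
#' waveforms in \[-1, 1\]. Deterministic given its parameters and input.
#'
#' @param cfg a [gan_config].
#' @param seed parameter-initialization seed.
#' @param params optional explicit parameter list (e.g. from a checkpoint).
#' @return A function of class `wavegan_generator`; its parameters are
#'   available as `attr(, "params")`.
#' @export
build_generator <- function(cfg = gan_config(), seed = 1L, params = NULL) {
  if (is.null(params)) params <- gan_init_generator(cfg, seed)
  f <- function(z) {
    out <- gan_generator_fwd(params, cfg, z)
    matrix(out, nrow = cfg$output_len)
  }
  attr(f, "params") <- params
  attr(f, "cfg") <- cfg
  class(f) <- c("wavegan_generator", "function")
  f
}

#' Build a WaveGAN critic
#'
#' Returns a callable critic scoring waveform batches (`output_len x B`
#' matrix -> `B` real scores). Phase-shuffle layers apply per-sample
#' circular shifts drawn uniformly from
#' \[-`phase_shuffle_n`, `phase_shuffle_n`\] using R's RNG, so scores are
#' deterministic when `phase_shuffle_n = 0` or under a fixed seed.
#'
#' @param cfg a [gan_config].
#' @param seed parameter-initialization seed.
#' @param params optional explicit parameter list.
#' @return A function of class `wavegan_critic` with `attr(, "params")`.
#' @export
build_discriminator <- function(cfg = gan_config(), seed = 1L, params = NULL) {
  if (is.null(params)) params <- gan_init_critic(cfg, seed)
  f <- function(x, shifts = NULL) {
    if (is.matrix(x) && nrow(x) != cfg$output_len)
      stopf("critic expects clips of %d samples, got %d",
            cfg$output_len, nrow(x))
    x <- array(as.matrix(x), dim = c(cfg$output_len, 1L,
                                     ncol(as.matrix(x))))
    if (is.null(shifts)) shifts <- gan_draw_shifts(cfg, dim(x)[3])
    gan_critic_fwd(params, cfg, x, shifts)
  }
  attr(f, "params") <- params
  attr(f, "cfg") <- cfg
  class(f) <- c("wavegan_critic", "function")
  f
}

#' WGAN gradient penalty
#'
#' The Wasserstein-GAN-with-gradient-penalty regularizer:
#' `lambda * mean_b (||grad_x critic(x_b)||_2 - 1)^2`, evaluated at random
#' interpolates `x_b = e_b * real_b + (1 - e_b) * fake_b` with `e_b ~
#' Uniform(0, 1)` per clip. For critics built by [build_discriminator] the
#' input gradient is computed by exact backpropagation (with phase shuffle
#' disabled so the map is differentiable); for an arbitrary function either
#' supply `grad_fn` or a central finite difference is used.
#'
#' @param critic a `wavegan_critic` or any function mapping an
#'   `L x B` matrix to `B` scores.
#' @param real_batch,fake_batch `L x B` numeric matrices (equal shapes).
#' @param gp_lambda penalty weight.
#' @param seed seed for the interpolation coefficients.
#' @param grad_fn optional function returning the `L x B` matrix of
#'   per-clip input gradients.
#' @param fd_step finite-difference step when no gradient is available.
#' @return The scalar penalty.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, gp_lambda = 10,
                             seed = 1L, grad_fn = NULL, fd_step = 1e-5) {
  real_batch <- as.matrix(real_batch); fake_batch <- as.matrix(fake_batch)
  stopifnot(identical(dim(real_batch), dim(fake_batch)))
  B <- ncol(real_batch)
  e <- with_seed(derive_seed(seed, "gp-interp"), stats::runif(B))
  xhat <- sweep(real_batch, 2, e, "*") + sweep(fake_batch, 2, 1 - e, "*")
  g <- if (inherits(critic, "wavegan_critic")) {
    params <- attr(critic, "params"); cfg <- attr(critic, "cfg")
    xa <- array(xhat, dim = c(nrow(xhat), 1L, B))
    fwd <- gan_critic_fwd(params, cfg, xa, shifts = NULL, cache = TRUE)
    bwd <- gan_critic_bwd(params, cfg, fwd, rep(1, B),
                          need_input_grad = TRUE, need_weight_grad = FALSE)
    matrix(bwd$gx, nrow = nrow(xhat))
  } else if (!is.null(grad_fn)) {
    as.matrix(grad_fn(xhat))
  } else {
    num_input_grad(critic, xhat, fd_step)
  }
  norms <- sqrt(colSums(g^2))
  gp_lambda * mean((norms - 1)^2)
}

# Central finite-difference per-clip input gradient of a batch critic.
#' @keywords internal
num_input_grad <- function(critic, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) {
    xp <- x; xm <- x
    xp[i, ] <- xp[i, ] + h
    xm[i, ] <- xm[i, ] - h
    g[i, ] <- (critic(xp) - critic(xm)) / (2 * h)
  }
  g
}

#' Train a WaveGAN on one event class
#'
#' Wasserstein-GAN-with-gradient-penalty training of the raw-waveform
#' generator/critic pair on a single-class [segment_set]: `n_critic` critic
#' updates (WGAN-GP loss, Adam) per generator update, phase shuffle in the
#' critic, and a checkpoint — generator parameters plus
#' `checkpoint_samples` generated clips — every `checkpoint_every`
#' iterations. The parameter gradient of the penalty term (a second-order
#' quantity) is computed with a central finite-difference Hessian-vector
#' product along the input-gradient direction.
#'
#' Training is deterministic given `cfg$seed`; a non-finite loss aborts
#' with the failing iteration named.
#'
#' @param data a [segment_set] whose clips all have `output_len` samples
#'   (typically a single event class).
#' @param cfg a [gan_config].
#' @param verbose print a progress line every checkpoint.
#' @return An object of class `wavegan`: checkpoint series, loss traces
#'   (`$trace`: iteration, critic_loss, gen_loss, gp, wasserstein), final
#'   parameters, sampling rate and training label.
#' @export
wavegan_train <- function(data, cfg = gan_config(), verbose = FALSE) {
  stopifnot(inherits(data, "segment_set"))
  if (length(data) == 0L) stopf("wavegan_train: empty training set")
  if (nrow(data$segments) != cfg$output_len)
    stopf("clips have %d samples but cfg$output_len is %d",
          nrow(data$segments), cfg$output_len)
  X <- data$segments
  n <- ncol(X)
  B <- cfg$batch_size

  with_seed(derive_seed(cfg$seed, "train"), {
    gp_ <- gan_init_generator(cfg, cfg$seed)
    cp_ <- gan_init_critic(cfg, cfg$seed)
    opt_g <- adam_init(gp_); opt_c <- adam_init(cp_)
    trace <- vector("list", cfg$iterations)
    checkpoints <- list()

    for (it in seq_len(cfg$iterations)) {
      c_loss <- gp_val <- w_est <- NA_real_
      for (j in seq_len(cfg$n_critic)) {
        idx <- sample.int(n, B, replace = TRUE)
        real <- array(X[, idx], dim = c(cfg$output_len, 1L, B))
        z <- matrix(stats::runif(cfg$latent_dim * B, -1, 1), cfg$latent_dim)
        fake <- gan_generator_fwd(gp_, cfg, z)

        sh_f <- gan_draw_shifts(cfg, B)
        f_fake <- gan_critic_fwd(cp_, cfg, fake, sh_f, cache = TRUE)
        b_fake <- gan_critic_bwd(cp_, cfg, f_fake, rep(1 / B, B))
        sh_r <- gan_draw_shifts(cfg, B)
        f_real <- gan_critic_fwd(cp_, cfg, real, sh_r, cache = TRUE)
        b_real <- gan_critic_bwd(cp_, cfg, f_real, rep(-1 / B, B))

        gpg <- gan_gp_grads(cp_, cfg, real, fake)

        grads <- Map(function(a, b) a + b, b_fake$grads, b_real$grads)
        grads <- Map(function(a, b) a + b, grads, gpg$grads[names(grads)])
        upd <- adam_step(cp_, grads, opt_c, cfg$adam_lr, cfg$adam_beta1,
                         cfg$adam_beta2)
        cp_ <- upd$params; opt_c <- upd$state

        w_est <- mean(f_real$scores) - mean(f_fake$scores)
        gp_val <- gpg$penalty
        c_loss <- mean(f_fake$scores) - mean(f_real$scores) + gp_val
      }

      z <- matrix(stats::runif(cfg$latent_dim * B, -1, 1), cfg$latent_dim)
      fg <- gan_generator_fwd(gp_, cfg, z, cache = TRUE)
      sh <- gan_draw_shifts(cfg, B)
      fd <- gan_critic_fwd(cp_, cfg, fg$out, sh, cache = TRUE)
      bd <- gan_critic_bwd(cp_, cfg, fd, rep(-1 / B, B),
                           need_input_grad = TRUE, need_weight_grad = FALSE)
      ggrads <- gan_generator_bwd(gp_, cfg, fg, bd$gx)
      updg <- adam_step(gp_, ggrads, opt_g, cfg$adam_lr, cfg$adam_beta1,
                        cfg$adam_beta2)
      gp_ <- updg$params; opt_g <- updg$state
      g_loss <- -mean(fd$scores)

      if (!all(is.finite(c(c_loss, g_loss, gp_val))))
        stopf("non-finite loss at iteration %d (critic %.3g, gen %.3g, gp %.3g)",
              it, c_loss, g_loss, gp_val)
      trace[[it]] <- c(iteration = it, critic_loss = c_loss,
                       gen_loss = g_loss, gp = gp_val, wasserstein = w_est)

      if (it %% cfg$checkpoint_every == 0L) {
        zc <- with_seed(derive_seed(cfg$seed, "ckpt-samples", it),
                        matrix(stats::runif(cfg$latent_dim *
                                              cfg$checkpoint_samples, -1, 1),
                               cfg$latent_dim))
        samples <- matrix(gan_generator_fwd(gp_, cfg, zc),
                          nrow = cfg$output_len)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(iteration = it, params = gp_, samples = samples)
        if (verbose)
          message(sprintf("[wavegan] iter %d: W = %.4f, gp = %.4f",
                          it, w_est, gp_val))
      }
    }

    structure(list(cfg = cfg,
                   checkpoints = checkpoints,
                   trace = as.data.frame(do.call(rbind, trace)),
                   params = gp_, critic_params = cp_,
                   rate = data$rate, label = data$labels[1]),
              class = "wavegan")
  })
}

# Parameter gradients of the WGAN-GP penalty term, via a central
# finite-difference Hessian-vector product along the per-clip unit
# input-gradient direction (two extra backward passes).
#' @keywords internal
gan_gp_grads <- function(cp_, cfg, real, fake, delta = 1e-3) {
  B <- dim(real)[3]
  e <- stats::runif(B)
  xhat <- real * rep(e, each = cfg$output_len) +
    fake * rep(1 - e, each = cfg$output_len)
  sh <- gan_draw_shifts(cfg, B)
  fwd <- gan_critic_fwd(cp_, cfg, xhat, sh, cache = TRUE)
  bwd <- gan_critic_bwd(cp_, cfg, fwd, rep(1, B),
                        need_input_grad = TRUE, need_weight_grad = FALSE)
  g <- bwd$gx
  norms <- sqrt(apply(g^2, 3, sum))
  penalty <- cfg$gp_lambda * mean((norms - 1)^2)
  if (cfg$gp_lambda == 0) {
    zero <- lapply(cp_, function(p) p * 0)
    return(list(penalty = penalty, grads = zero))
  }
  u <- g / rep(pmax(norms, 1e-12), each = cfg$output_len)
  coef <- 2 * cfg$gp_lambda * (norms - 1) / B
  fp <- gan_critic_fwd(cp_, cfg, xhat + delta * u, sh, cache = TRUE)
  bp <- gan_critic_bwd(cp_, cfg, fp, coef / (2 * delta))
  fm <- gan_critic_fwd(cp_, cfg, xhat - delta * u, sh, cache = TRUE)
  bm <- gan_critic_bwd(cp_, cfg, fm, -coef / (2 * delta))
  list(penalty = penalty,
       grads = Map(function(a, b) a + b, bp$grads, bm$grads))
}

#' @export
print.wavegan <- function(x, ...) {
  cat(sprintf("<wavegan> trained %d iterations on %d-sample clips (label '%s')\n",
              x$cfg$iterations, x$cfg$output_len, x$label))
  cat(sprintf("  model_size %d, latent %d, %d checkpoint(s)\n",
              x$cfg$model_size, x$cfg$latent_dim, length(x$checkpoints)))
  if (nrow(x$trace))
    cat(sprintf("  final Wasserstein estimate %.4f\n",
                x$trace$wasserstein[nrow(x$trace)]))
  invisible(x)
}

#' @export
plot.wavegan <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$wasserstein, type = "l",
                 xlab = "iteration", ylab = "Wasserstein estimate",
                 main = "WaveGAN critic trace", ...)
  invisible(x)
}

#' Generate clips from a trained WaveGAN
#'
#' Draws latent codes from the training latent distribution and decodes
#' them; deterministic given `(model/checkpoint, seed)`.
#'
#' @param model a [wavegan_train] result, or one element of its
#'   `$checkpoints` list.
#' @param n number of clips.
#' @param seed sampling seed.
#' @param checkpoint optional checkpoint iteration to generate from (the
#'   final parameters are used when omitted).
#' @param cfg,rate required only when `model` is a bare checkpoint.
#' @return A [segment_set] labeled `"synthetic"`.
#' @export
wavegan_generate <- function(model, n, seed = 1L, checkpoint = NULL,
                             cfg = NULL, rate = NULL) {
  stopifnot(n >= 1)
  if (inherits(model, "wavegan")) {
    cfg <- model$cfg; rate <- model$rate
    params <- if (is.null(checkpoint)) model$params else {
      its <- vapply(model$checkpoints, `[[`, 0, "iteration")
      hit <- which(its == checkpoint)
      if (!length(hit)) stopf("no checkpoint at iteration %d", checkpoint)
      model$checkpoints[[hit]]$params
    }
  } else {
    if (is.null(cfg) || is.null(rate))
      stopf("cfg and rate are required with a bare checkpoint")
    params <- model$params
  }
  z <- with_seed(derive_seed(seed, "generate"),
                 matrix(stats::runif(cfg$latent_dim * n, -1, 1),
                        cfg$latent_dim))
  out <- matrix(0, cfg$output_len, n)
  for (start in seq(1L, n, by = 64L)) {      # decode in small batches
    sel <- start:min(n, start + 63L)
    out[, sel] <- matrix(gan_generator_fwd(params, cfg,
                                           z[, sel, drop = FALSE]),
                         nrow = cfg$output_len)
  }
  segment_set(out, "synthetic", rate, source_id = "wavegan",
              segment_index = seq_len(n))
}

#' Select the converged checkpoint by reference classification
#'
#' Classifies each checkpoint's stored sample clips with a reference
#' classifier trained on real data and returns the checkpoint whose clips
#' are most often assigned `target_label`; ties go to the earliest
#' iteration.
#'
#' @param model a [wavegan_train] result (its checkpoint series).
#' @param ref_classifier an [lda_svm] model.
#' @param target_label the event class the GAN was trained on.
#' @return List with `iteration`, `checkpoint`, and the per-checkpoint
#'   correct-count vector `counts`.
#' @export
select_converged <- function(model, ref_classifier, target_label) {
  stopifnot(inherits(model, "wavegan"))
  if (length(model$checkpoints) == 0L)
    stopf("select_converged: empty checkpoint series")
  counts <- vapply(model$checkpoints, function(ck) {
    s <- segment_set(ck$samples, "synthetic", model$rate)
    sum(predict(ref_classifier, s) == target_label)
  }, 0L)
  best <- which.max(counts)                   # ties -> earliest
  list(iteration = model$checkpoints[[best]]$iteration,
       checkpoint = model$checkpoints[[best]], counts = counts)
}
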