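# Internal layer engine for the raw-waveform GAN: forward passes with
# cached intermediates, hand-written reverse-mode gradients over the Rcpp
# conv1d kernels, and Adam. Arrays are (L, C, B); conv weights (K, Ci, Co);
# transposed-conv weights (K, Cout, Cin) since the layer is the conv adjoint.

KERNEL_PAD <- function(kernel_len) (kernel_len - 1L) %/% 2L  # 25 -> 12

# y (Lo, Co, B) from x (L, Ci, B); the GEMM runs in BLAS.
#' @keywords internal
nn_conv_fwd <- function(x, W, b, stride, pad) {
  d <- dim(x); dw <- dim(W)
  Lo <- (d[1] + 2L * pad - dw[1]) %/% stride + 1L
  cols <- im2col1d(x, d[1], d[2], d[3], dw[1], stride, pad)
  y <- crossprod(matrix(W, dw[1] * dw[2], dw[3]), cols) + b   # (Co, Lo*B)
  aperm(array(y, dim = c(dw[3], Lo, d[3])), c(2, 1, 3))
}

#' @keywords internal
nn_conv_bwd_input <- function(gy, W, L, stride, pad) {
  dg <- dim(gy); dw <- dim(W)
  gmat <- matrix(aperm(gy, c(2, 1, 3)), dw[3])                # (Co, Lo*B)
  cols <- matrix(W, dw[1] * dw[2], dw[3]) %*% gmat
  col2im1d(cols, L, dw[2], dg[3], dw[1], stride, pad)
}

#' @keywords internal
nn_conv_bwd_weight <- function(x, gy, kernel_len, stride, pad) {
  d <- dim(x); dg <- dim(gy)
  cols <- im2col1d(x, d[1], d[2], d[3], kernel_len, stride, pad)
  gmat <- matrix(aperm(gy, c(2, 1, 3)), dg[2])                # (Co, Lo*B)
  array(tcrossprod(cols, gmat), dim = c(kernel_len, d[2], dg[2]))
}

# Transposed conv (stride-s upsampling), the adjoint of nn_conv_fwd:
# input (L, Cin, B) -> output (s*L, Cout, B); W is (K, Cout, Cin).
#' @keywords internal
nn_tconv_fwd <- function(x, W, b, stride, pad) {
  y <- nn_conv_bwd_input(x, W, L = stride * dim(x)[1], stride, pad)
  sweep_channels_add(y, b)
}

# y (L, C, B) + per-channel bias
#' @keywords internal
sweep_channels_add <- function(y, b) {
  d <- dim(y)
  y + rep(rep(b, each = d[1]), times = d[3])
}

# branchless: 0.5(1+a)x + 0.5(1-a)|x|
#' @keywords internal
nn_lrelu <- function(x, slope = 0.2)
  0.5 * (1 + slope) * x + 0.5 * (1 - slope) * abs(x)
#' @keywords internal
nn_lrelu_grad <- function(x, g, slope = 0.2)
  g * (slope + (1 - slope) * (x > 0))

# Circular time shift per sample: y[t] = x[t - s (mod L)], s in shifts (len B).
# Samples sharing a shift value are moved together (shifts are small ints).
#' @keywords internal
nn_phase_shift <- function(x, shifts) {
  d <- dim(x)
  for (s0 in unique(shifts)) {
    s <- s0 %% d[1]
    if (s == 0) next
    sel <- which(shifts == s0)
    idx <- c((d[1] - s + 1L):d[1], seq_len(d[1] - s))
    x[, , sel] <- x[idx, , sel, drop = FALSE]
  }
  x
}

# ---------------------------------------------------------------------------
# Generator: dense (latent -> 16 x c0), ReLU, then n transposed-conv layers
# (stride 4, kernel 25), ReLU between, tanh on the last (1-channel) layer.

#' @keywords internal
gan_layer_channels <- function(cfg) {
  n <- cfg$n_layers
  c0 <- cfg$model_size * 2^(n - 1L)
  gen <- c(c0, cfg$model_size * 2^((n - 2L):0), 1L)[seq_len(n + 1L)]
  if (n == 1L) gen <- c(c0, 1L)
  critic <- c(1L, cfg$model_size * 2^(0:(n - 1L)))
  list(c0 = c0, gen = gen, critic = critic)
}

#' @keywords internal
gan_init_generator <- function(cfg, seed) {
  ch <- gan_layer_channels(cfg)
  with_seed(derive_seed(seed, "gen-init"), {
    p <- list(
      dense_W = matrix(stats::rnorm(cfg$latent_dim * 16L * ch$c0, 0, 0.02),
                       cfg$latent_dim, 16L * ch$c0),
      dense_b = numeric(16L * ch$c0))
    for (i in seq_len(cfg$n_layers)) {
      cin <- ch$gen[i]; cout <- ch$gen[i + 1L]
      p[[sprintf("tconv%d_W", i)]] <-
        array(stats::rnorm(cfg$kernel_len * cout * cin, 0, 0.02),
              dim = c(cfg$kernel_len, cout, cin))
      p[[sprintf("tconv%d_b", i)]] <- numeric(cout)
    }
    p
  })
}

#' @keywords internal
gan_generator_fwd <- function(params, cfg, z, cache = FALSE) {
  if (!is.matrix(z)) z <- matrix(z, nrow = cfg$latent_dim)
  B <- ncol(z)
  ch <- gan_layer_channels(cfg)
  pad <- KERNEL_PAD(cfg$kernel_len)
  h_pre <- crossprod(params$dense_W, z) + params$dense_b   # (16*c0) x B
  h <- pmax(h_pre, 0)
  x <- array(h, dim = c(16L, ch$c0, B))
  acts <- if (cache) list(z = z, dense_pre = h_pre) else NULL
  pres <- list()
  ins <- list()
  for (i in seq_len(cfg$n_layers)) {
    if (cache) ins[[i]] <- x
    y <- nn_tconv_fwd(x, params[[sprintf("tconv%d_W", i)]],
                      params[[sprintf("tconv%d_b", i)]], cfg$stride, pad)
    if (cache) pres[[i]] <- y
    x <- if (i < cfg$n_layers) pmax(y, 0) else tanh(y)
  }
  out <- x                                                  # (output_len,1,B)
  if (cache) list(out = out, acts = acts, pres = pres, ins = ins) else out
}

# gy: gradient w.r.t. generator output (L, 1, B). Returns named grads.
#' @keywords internal
gan_generator_bwd <- function(params, cfg, fwd, gy) {
  pad <- KERNEL_PAD(cfg$kernel_len)
  g <- gy
  grads <- list()
  for (i in rev(seq_len(cfg$n_layers))) {
    pre <- fwd$pres[[i]]
    g <- if (i < cfg$n_layers) g * (pre > 0) else g * (1 - tanh(pre)^2)
    W <- params[[sprintf("tconv%d_W", i)]]
    grads[[sprintf("tconv%d_b", i)]] <- apply(g, 2, sum)
    # tconv is the conv adjoint: dW = conv_bwd_weight(g, x_in); dx = conv_fwd(g, W)
    grads[[sprintf("tconv%d_W", i)]] <-
      nn_conv_bwd_weight(g, fwd$ins[[i]], cfg$kernel_len, cfg$stride, pad)
    g <- nn_conv_fwd(g, W, numeric(dim(W)[3]), cfg$stride, pad)
  }
  h_g <- matrix(g, nrow = prod(dim(g)[1:2]))               # (16*c0) x B
  h_g <- h_g * (fwd$acts$dense_pre > 0)
  grads$dense_b <- rowSums(h_g)
  grads$dense_W <- fwd$acts$z %*% t(h_g)
  grads
}

# ---------------------------------------------------------------------------
# Critic: n strided conv layers (stride 4, kernel 25) with LeakyReLU(0.2)
# and phase shuffle after each hidden layer, then flatten -> dense -> scalar.

#' @keywords internal
gan_init_critic <- function(cfg, seed) {
  ch <- gan_layer_channels(cfg)
  with_seed(derive_seed(seed, "critic-init"), {
    p <- list()
    for (i in seq_len(cfg$n_layers)) {
      cin <- ch$critic[i]; cout <- ch$critic[i + 1L]
      p[[sprintf("conv%d_W", i)]] <-
        array(stats::rnorm(cfg$kernel_len * cin * cout, 0, 0.02),
              dim = c(cfg$kernel_len, cin, cout))
      p[[sprintf("conv%d_b", i)]] <- numeric(cout)
    }
    p$dense_W <- matrix(stats::rnorm(16L * ch$c0, 0, 0.02), 16L * ch$c0, 1L)
    p$dense_b <- 0
    p
  })
}

# Draw per-layer, per-sample phase-shuffle shifts for one critic application.
#' @keywords internal
gan_draw_shifts <- function(cfg, B) {
  if (cfg$phase_shuffle_n == 0L) return(NULL)
  lapply(seq_len(cfg$n_layers - 1L), function(i)
    sample.int(2L * cfg$phase_shuffle_n + 1L, B, replace = TRUE) -
      cfg$phase_shuffle_n - 1L)
}

#' @keywords internal
gan_critic_fwd <- function(params, cfg, x, shifts = NULL, cache = FALSE) {
  pad <- KERNEL_PAD(cfg$kernel_len)
  if (length(dim(x)) != 3L) x <- array(x, dim = c(nrow(x), 1L, ncol(x)))
  ins <- list(); pres <- list()
  h <- x
  for (i in seq_len(cfg$n_layers)) {
    if (cache) ins[[i]] <- h
    y <- nn_conv_fwd(h, params[[sprintf("conv%d_W", i)]],
                     params[[sprintf("conv%d_b", i)]], cfg$stride, pad)
    if (cache) pres[[i]] <- y
    h <- nn_lrelu(y)
    if (i < cfg$n_layers && !is.null(shifts))
      h <- nn_phase_shift(h, shifts[[i]])
  }
  flat <- matrix(h, nrow = prod(dim(h)[1:2]))
  scores <- as.numeric(crossprod(flat, params$dense_W)) + params$dense_b
  if (cache) list(scores = scores, ins = ins, pres = pres, flat = flat,
                  dims = dim(h), shifts = shifts)
  else scores
}

# gscore: d(loss)/d(score), length B. Returns list(grads =, gx =).
#' @keywords internal
gan_critic_bwd <- function(params, cfg, fwd, gscore, need_input_grad = FALSE,
                           need_weight_grad = TRUE) {
  pad <- KERNEL_PAD(cfg$kernel_len)
  grads <- list()
  if (need_weight_grad) {
    grads$dense_W <- fwd$flat %*% matrix(gscore, ncol = 1L)
    grads$dense_b <- sum(gscore)
  }
  gflat <- params$dense_W %*% matrix(gscore, nrow = 1L)    # (16c0) x B
  g <- array(gflat, dim = fwd$dims)
  for (i in rev(seq_len(cfg$n_layers))) {
    if (i < cfg$n_layers && !is.null(fwd$shifts))
      g <- nn_phase_shift(g, -fwd$shifts[[i]])
    g <- nn_lrelu_grad(fwd$pres[[i]], g)
    W <- params[[sprintf("conv%d_W", i)]]
    if (need_weight_grad) {
      grads[[sprintf("conv%d_b", i)]] <- apply(g, 2, sum)
      grads[[sprintf("conv%d_W", i)]] <-
        nn_conv_bwd_weight(fwd$ins[[i]], g, cfg$kernel_len, cfg$stride, pad)
    }
    if (i > 1L || need_input_grad)
      g <- nn_conv_bwd_input(g, W, L = dim(fwd$ins[[i]])[1], cfg$stride, pad)
  }
  list(grads = grads, gx = if (need_input_grad) g else NULL)
}

# ---------------------------------------------------------------------------
# Adam

#' @keywords internal
adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

#' @keywords internal
adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
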