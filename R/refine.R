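#' Markov-chain refinement configuration
#'
#' Settings for the Metropolis-Hastings stage that moves the pool of
#' GAN-generated clips toward the acoustic-feature distribution of real
#' recordings.
#'
#' @param beta balance parameter in \[0, 1\]: the proposal
#'   `theta_prop = (1 - beta) (v - s_t) + beta (v - r_t)` trades smoothness
#'   of transition from the current synthetic state (`beta -> 0`) against
#'   similarity to a real sample (`beta -> 1`).
#' @param n_out number of accepted clips to produce.
#' @param ema_alpha exponential-moving-average weight in (0, 1\] applied to
#'   accepted feature vectors (default 0.2); 1 disables smoothing.
#' @param max_iters proposal budget before giving up (default `50 * n_out`).
#' @param seed chain seed.
#' @param prior_on support of the Gaussian prior `p(.)`: `"transitions"`
#'   (default) fits it on differences of randomly paired real feature
#'   vectors; `"features"` fits it on the raw real feature vectors.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(beta, n_out, ema_alpha = 0.2,
                          max_iters = 50L * n_out, seed = 1L,
                          prior_on = c("transitions", "features")) {
  if (beta < 0 || beta > 1) stopf("beta must lie in [0, 1]")
  stopifnot(n_out >= 1, ema_alpha > 0, ema_alpha <= 1, max_iters >= 1)
  structure(list(beta = beta, n_out = as.integer(n_out),
                 ema_alpha = ema_alpha, max_iters = as.integer(max_iters),
                 seed = as.integer(seed), prior_on = match.arg(prior_on)),
            class = "refine_config")
}

#' Proposal transition vector
#'
#' `theta_prop = (1 - beta) (v - s_t) + beta (v - r_t)`, elementwise: the
#' beta-weighted combination of the candidate's offset from the current
#' synthetic feature state and its offset from a real feature vector.
#'
#' @param v candidate feature vector (drawn from the generated pool).
#' @param s_t current synthetic feature vector.
#' @param r_t real feature vector drawn at this iteration.
#' @param beta balance parameter in \[0, 1\].
#' @return The proposed transition vector.
#' @export
transition_vector <- function(v, s_t, r_t, beta) {
  if (length(v) != length(s_t) || length(v) != length(r_t))
    stopf("transition_vector: dimension mismatch")
  if (beta < 0 || beta > 1) stopf("beta must lie in [0, 1]")
  (1 - beta) * (v - s_t) + beta * (v - r_t)
}

#' Metropolis-Hastings acceptance probability
#'
#' `alpha = min(1, p(theta_prop) / p(theta_t))` under the Gaussian prior,
#' computed in log space for stability. Always in \[0, 1\], and invariant
#' to any positive rescaling of the prior density (only the ratio enters).
#'
#' @param theta_prop proposed transition vector.
#' @param theta_t current chain state.
#' @param prior a [fit_gaussian_prior] result.
#' @return The acceptance probability.
#' @export
acceptance_probability <- function(theta_prop, theta_t, prior) {
  lp <- prior_logpdf(prior, theta_prop)
  lc <- prior_logpdf(prior, theta_t)
  if (!is.finite(lp) || !is.finite(lc))
    stopf("non-finite prior density in acceptance_probability")
  exp(min(0, lp - lc))
}

#' Exponential-moving-average smoothing of accepted features
#'
#' `ema_alpha * new + (1 - ema_alpha) * prev`; the first accepted sample
#' initializes the accumulator to itself (pass `prev = NULL`).
#'
#' @param prev previous accumulator (or `NULL` at the first acceptance).
#' @param new newly accepted feature vector.
#' @param ema_alpha smoothing weight in (0, 1\].
#' @return The updated accumulator.
#' @export
ema_smooth <- function(prev, new, ema_alpha) {
  if (is.null(prev)) return(new)
  if (length(prev) != length(new)) stopf("ema_smooth: dimension mismatch")
  ema_alpha * new + (1 - ema_alpha) * prev
}

#' Initialize a refinement chain state
#'
#' The chain starts from its own proposal distribution, as is standard for
#' Metropolis-Hastings: the initial synthetic state `s_0` is a randomly
#' drawn pool feature vector and `theta_0` is one draw of the transition
#' vector `(1 - beta)(v0 - s0) + beta (v0 - r0)` with `v0` from the pool
#' and `r0` from the real set. Starting the chain instead from a state of
#' much higher prior density than any reachable proposal (e.g. a real-data
#' transition when the generated pool lies far from the real feature
#' manifold) would freeze it — every proposal rejected, the budget
#' exhausted with zero acceptances — so the proposal-based start is used
#' throughout. RNG is R's global stream; seed at the caller.
#'
#' @param pool_features,real_features feature matrices (one row per clip).
#' @param beta balance parameter of the proposal.
#' @return An object of class `chain_state`.
#' @export
chain_init <- function(pool_features, real_features, beta) {
  np <- nrow(pool_features)
  ij <- sample.int(np, 2L, replace = np < 2L)
  r0 <- real_features[sample.int(nrow(real_features), 1L), ]
  s0 <- pool_features[ij[1L], ]
  v0 <- pool_features[ij[2L], ]
  structure(list(theta = transition_vector(v0, s0, r0, beta),
                 s = s0,
                 ema = NULL, accepted_idx = integer(0),
                 accepted_feat = list(), t = 0L, n_accept = 0L),
            class = "chain_state")
}

#' One Metropolis-Hastings refinement step
#'
#' Draws a candidate `v` uniformly from the pool and `r_t` uniformly from
#' the real set, forms the transition vector and its acceptance probability
#' under the prior, draws `u ~ Uniform(0, 1)`, and accepts iff `u < alpha`.
#' On acceptance the chain moves (`theta <- theta_prop`, `s <- v`), the EMA
#' accumulator absorbs `v`, and `(candidate index, smoothed features)` is
#' appended; otherwise only the iteration counter advances.
#'
#' @param state a [chain_init] state.
#' @param pool_features,real_features feature matrices.
#' @param prior a [fit_gaussian_prior] result.
#' @param cfg a [refine_config].
#' @return The updated `chain_state`.
#' @export
mh_step <- function(state, pool_features, real_features, prior, cfg) {
  i_v <- sample.int(nrow(pool_features), 1L)
  i_r <- sample.int(nrow(real_features), 1L)
  v <- pool_features[i_v, ]
  theta_prop <- transition_vector(v, state$s, real_features[i_r, ], cfg$beta)
  alpha <- acceptance_probability(theta_prop, state$theta, prior)
  u <- stats::runif(1)
  if (u < alpha) {
    state$theta <- theta_prop
    state$s <- v
    state$ema <- ema_smooth(state$ema, v, cfg$ema_alpha)
    state$n_accept <- state$n_accept + 1L
    state$accepted_idx[state$n_accept] <- i_v
    state$accepted_feat[[state$n_accept]] <- state$ema
  }
  state$t <- state$t + 1L
  state
}

#' Feature-level Metropolis-Hastings refinement
#'
#' The refinement core, operating purely on feature matrices: fits the
#' Gaussian prior on the real features (on transition differences by
#' default, per `cfg$prior_on`), initializes the chain, and iterates
#' [mh_step] until `n_out` acceptances or the `max_iters` budget is
#' exhausted (the latter warns and returns a partial result).
#'
#' @param pool_features,real_features numeric matrices, one feature vector
#'   per row (generated pool and real reference).
#' @param cfg a [refine_config].
#' @param prior optional pre-fitted [fit_gaussian_prior]; fitted from
#'   `real_features` when omitted.
#' @return List: `indices` (accepted pool rows, in acceptance order),
#'   `features` (matrix of EMA-smoothed accepted feature vectors),
#'   `acceptance_rate`, `prior`, `proposals`.
#' @export
refine_features <- function(pool_features, real_features, cfg, prior = NULL) {
  pool_features <- as.matrix(pool_features)
  real_features <- as.matrix(real_features)
  if (nrow(pool_features) == 0L || nrow(real_features) == 0L)
    stopf("refine_features: empty pool or real set")
  if (is.null(prior)) {
    support <- switch(cfg$prior_on,
      transitions = transition_sample(real_features, seed = cfg$seed),
      features = real_features)
    prior <- fit_gaussian_prior(support)
  }
  with_seed(derive_seed(cfg$seed, "chain"), {
    state <- chain_init(pool_features, real_features, cfg$beta)
    while (state$n_accept < cfg$n_out && state$t < cfg$max_iters)
      state <- mh_step(state, pool_features, real_features, prior, cfg)
    if (state$n_accept < cfg$n_out)
      warnf("refinement budget exhausted: %d of %d accepted (acceptance rate %.3f)",
            state$n_accept, cfg$n_out, state$n_accept / state$t)
    list(indices = state$accepted_idx,
         features = do.call(rbind, state$accepted_feat),
         acceptance_rate = state$n_accept / state$t,
         prior = prior, proposals = state$t)
  })
}

#' Refine a pool of generated clips toward the real feature distribution
#'
#' Extracts refinement features for the generated pool and the real
#' reference set, runs the Metropolis-Hastings chain in feature space, and
#' emits the accepted candidates. The refinement operates on features; no
#' feature-to-waveform inversion exists, so the emitted audio is the
#' accepted pool clip itself (candidates may repeat) while the EMA-smoothed
#' feature vector is recorded alongside as metadata.
#'
#' @param pool a [segment_set] of generated clips.
#' @param reals a [segment_set] of real (or fixture) clips of the target
#'   class.
#' @param cfg a [refine_config].
#' @param feature_cfg a [feature_config].
#' @return An object of class `refined_set`: `clips` (a [segment_set],
#'   labeled like `reals`), `features`, `indices`, `acceptance_rate`,
#'   `beta`.
#' @export
refine <- function(pool, reals, cfg, feature_cfg = feature_config()) {
  stopifnot(inherits(pool, "segment_set"), inherits(reals, "segment_set"))
  if (length(pool) == 0L || length(reals) == 0L)
    stopf("refine: empty pool or real set")
  pf <- feature_matrix(pool, feature_cfg)
  rf <- feature_matrix(reals, feature_cfg)
  res <- refine_features(pf, rf, cfg)
  clips <- pool[res$indices]
  clips$labels <- rep_len(reals$labels[1], length(res$indices))
  structure(list(clips = clips, features = res$features,
                 indices = res$indices,
                 acceptance_rate = res$acceptance_rate,
                 beta = cfg$beta, prior = res$prior),
            class = "refined_set")
}

#' @export
print.refined_set <- function(x, ...) {
  cat(sprintf("<refined_set> %d clips (beta = %g, acceptance rate %.3f)\n",
              length(x$indices), x$beta, x$acceptance_rate))
  invisible(x)
}

#' Sweep the balance parameter beta
#'
#' Runs [refine] once per beta, classifies each refined set with a
#' reference classifier, and tabulates the per-class counts (each row sums
#' to `n_out`). The beta whose refined clips are most often assigned
#' `target_label` is reported as `beta_opt`.
#'
#' @param pool,reals [segment_set]s as in [refine].
#' @param betas numeric vector of balance parameters.
#' @param cfg a [refine_config] (its `beta` field is overridden per row).
#' @param ref_classifier an [lda_svm] model trained on real data.
#' @param target_label class the pool is supposed to represent (default:
#'   the label of `reals`).
#' @param feature_cfg a [feature_config].
#' @return List: `table` (data.frame: beta, one count column per class,
#'   acceptance_rate), `beta_opt`, and `refined` (per-beta refined sets).
#' @export
sweep_beta <- function(pool, reals, betas, cfg, ref_classifier,
                       target_label = reals$labels[1],
                       feature_cfg = feature_config()) {
  if (length(betas) == 0L) stopf("sweep_beta: no beta values")
  alphabet <- ref_classifier$classes
  rows <- vector("list", length(betas))
  refined <- vector("list", length(betas))
  for (i in seq_along(betas)) {
    cfg_i <- cfg; cfg_i$beta <- betas[i]
    rs <- refine(pool, reals, cfg_i, feature_cfg)
    refined[[i]] <- rs
    pred <- predict(ref_classifier, rs$clips)
    counts <- vapply(alphabet, function(cl) sum(pred == cl), 0L)
    rows[[i]] <- data.frame(beta = betas[i], t(counts),
                            acceptance_rate = rs$acceptance_rate)
  }
  tab <- do.call(rbind, rows)
  names(tab)[2:(1 + length(alphabet))] <- alphabet
  best <- which.max(tab[[target_label]])
  list(table = tab, beta_opt = betas[best], refined = refined)
}
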