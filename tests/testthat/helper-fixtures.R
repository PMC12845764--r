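# Shared desk-scale study configuration and memoized fixture data.
#
# The suite works at a reduced scale so the whole pipeline runs on one CPU:
# clips at 16384 Hz are standardized to 1024-sample segments at 8192 Hz
# (1/8 s), and the GAN uses a small-width 3-layer topology. The scientific
# checks are scale-free (identities, bounds, directional comparisons).

tiny_pre <- function() preprocess_config(target_rate = 8192,
                                         segment_len = 1024,
                                         band_high = 2000,
                                         frame_len = 512, hop = 256)

tiny_fx <- function() fixture_config(rate = 16384, duration = 5)

tiny_fc <- function() feature_config(frame_len = 256, hop = 128)

tiny_gan_cfg <- function(seed = 1L, iterations = 10L,
                         checkpoint_every = 5L, ...) {
  gan_config(latent_dim = 32, model_size = 4, output_len = 1024,
             batch_size = 8, iterations = iterations,
             checkpoint_every = checkpoint_every, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# Balanced three-class segment set: `n_clips` 5-s clips per class ->
# 40 * n_clips segments per class.
tiny_segs <- function(n_clips = 2L, seed = 1L) {
  key <- sprintf("segs_%d_%d", n_clips, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- gen_dataset(n_clips, tiny_fx(), seed = seed,
                                         pre = tiny_pre())
  .fixture_cache[[key]]
}

# A reference classifier fitted on tiny_segs(2, 1).
tiny_ref <- function() {
  if (is.null(.fixture_cache$ref))
    .fixture_cache$ref <- lda_svm(tiny_segs(), tiny_fc())
  .fixture_cache$ref
}

# A small trained GAN on the QueenPresent fixture class (memoized; used by
# several tests so it is trained once).
tiny_gan <- function() {
  if (is.null(.fixture_cache$gan)) {
    qp <- tiny_segs()[tiny_segs()$labels == "QueenPresent"]
    .fixture_cache$gan <- wavegan_train(qp, tiny_gan_cfg(seed = 11,
                                                         iterations = 10))
  }
  .fixture_cache$gan
}

# One-second sine waveform helper.
sine_wave <- function(freq, rate = 16384, dur = 1, amp = 1,
                      label = NA_character_) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur - 1 / rate, by = 1 / rate)),
           rate, label = label)
}
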