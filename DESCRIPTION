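Package: mcwavegan
Title: Markov-Chain-Refined WaveGAN Synthesis of Bee Bioacoustic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates event-specific beehive audio (queen-present,
    queen-absent) by training a raw-waveform generative adversarial
    network (WaveGAN, trained as a Wasserstein GAN with gradient penalty)
    on one-second hive-audio clips and refining its outputs with a
    Metropolis-Hastings Markov-chain stage that moves the generated pool
    toward the acoustic-feature distribution of real recordings.
    Includes the full evaluation harness: WAV preprocessing (resampling,
    silence trimming, band-pass filtering, segmentation), synthetic
    three-class hive-audio fixtures, MFCC / linear-discriminant / SVM
    event classification, beta sweeps, distributional realism
    diagnostics (frequency, amplitude and spectral-centroid histograms
    with Jensen-Shannon divergence), and class-imbalance augmentation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    MASS,
    e1071,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
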