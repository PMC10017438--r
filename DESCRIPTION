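Package: somnostage
Title: Deep-Learning Sleep Stage Classification for Polysomnography
Version: 0.1.0
Authors@R:
    person("Somnostage", "Developers", email = "somnostage@example.org",
           role = c("aut", "cre"))
Description: Automatic sleep staging of polysomnographic (PSG) recordings
    with a residual 1D convolutional network, a mixing/compression stage and
    a gated recurrent unit (GRU) for temporal context.  Includes EDF and
    hypnogram readers, the full preprocessing chain (zero-phase FIR band-pass,
    per-channel z-scoring, HEOG derivation, polyphase resampling to 2,560
    samples per 30-s epoch), channel-permutation and polarity-flip data
    augmentation, dual-mode (context-free and context-aware) training with
    class-weighted cross-entropy, certainty-based permutation consensus,
    streaming (real-time) inference, a full evaluation-metric suite (MCC,
    F1, Cohen's kappa, stage proportions, transition rates, light-sleep
    merging), and a synthetic PSG generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
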