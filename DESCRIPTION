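Package: spectran
Title: Multi-Scale Attention Networks for Near-Infrared Spectral Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multi-task regression of corn quality constituents (moisture,
    starch, oil, protein) from near-infrared absorbance spectra. Implements
    the SpecTran architecture -- multi-scale patch embedding, spectral
    positional encoding, multi-scale spectral attention, enhanced
    Transformer blocks with convolutional feed-forward sublayers,
    multi-path feature fusion, and hybrid task-specific/shared prediction
    heads -- together with four neural baselines (MLP, CNN, Transformer
    encoder, LSTM-Transformer hybrid), interpolation-based training-set
    augmentation, a composite multi-task loss with one-cycle learning-rate
    scheduling and early stopping, perturbation-based wavelength
    importance, attention-map extraction, and a synthetic corn-like
    spectra generator so the whole pipeline is testable without external
    data. All networks run on a small built-in reverse-mode automatic
    differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
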