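Package: eegbold
Title: EEG-to-BOLD Translation with an Interpretable Convolutional Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level translation of multichannel scalp EEG into the BOLD
    time series of a reward-related region of interest (ventral striatum).
    Provides a seeded synthetic simultaneous EEG-fMRI session generator with
    known spatio-spectral ground truth, final-stage preprocessing and
    hemodynamic alignment, an interpretable convolutional autoencoder (spatial
    and spectral filter branches feeding an encoder-decoder) with a
    self-contained training engine, a regularized linear band-power baseline,
    a statistical validation suite (phase-randomization surrogate nulls,
    control-region specificity, downsampling control, win/loss functional
    validity, paired group tests), and weight-based spatio-spectral
    interpretation of the trained branches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
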