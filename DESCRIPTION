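Package: nirparity
Title: Parity Classification of Wild Mosquitoes from Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the parity status (parous versus
    nulliparous) of wild mosquitoes from near-infrared absorbance
    spectra. Implements spectral windowing to the standard
    1851-dimensional feature space, stepwise (stacked) autoencoder
    compression to a small code (default 10 features), a one-hidden-layer
    feed-forward neural network classifier trained by Levenberg-Marquardt
    optimization, repeated Monte-Carlo 75/25 cross-validation with
    confusion-matrix metrics and ROC/AUC, cross-cohort independent
    testing, and a synthetic spectra generator for end-to-end testing
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
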