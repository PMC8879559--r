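Package: emgmpca
Title: Multiscale PCA Denoising and Feature Classification for Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-channel surface electromyography
    (sEMG) gesture classification built around multiscale principal component
    analysis (MPCA) denoising. Signals are decomposed per channel with an
    orthogonal discrete wavelet transform, each wavelet scale is filtered by
    PCA across channels, and scales are kept or discarded by Hotelling T-squared
    and squared-prediction-error (SPE) monitoring statistics with F- and
    normal-theory control limits. Three ten-dimensional feature families are
    extracted from raw and denoised trials (Yule-Walker/Levinson-Durbin
    autoregressive coefficients, level-9 wavelet scale energies, FastICA
    component energies) and compared under k-nearest-neighbour and Gaussian
    naive Bayes classification with stratified ten-fold cross-validation.
    A motor-unit action-potential-train (MUAPT) simulator generates labelled
    synthetic trial sets with crosstalk mixing, line interference and
    low-frequency firing instability, so the whole pipeline is testable
    without external recordings; a reader for the UCI two-channel hand-grasp
    MAT-v5 layout supports real-data runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ica,
    e1071,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
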