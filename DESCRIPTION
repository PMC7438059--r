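Package: ecogrip
Title: Movement Versus Force Representations in Motor-Cortical ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequential movement-force motor tasks recorded
    with high-density electrocorticography (ECoG). Extracts broadband low- and
    high-frequency band-power features (Hanning/FFT, log-normalized), decodes
    continuous finger kinematics and isometric force with ridge-regularized
    Wiener cascade models scored by cross-validated fractional variance
    accounted for, compares per-electrode decoding maps between behavioral
    modes (peak displacement and normalized map distance), denoises features
    with a Gaussian-emission sequential autoencoder that infers low-dimensional
    latent dynamics, summarizes population state with the neural vector angle,
    and classifies behavioral mode per 25-ms bin with permutation-based chance
    estimation. Includes a synthetic session generator with known ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    randomForest,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
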