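Package: spermqpi
Title: Simulated Quantitative Phase Imaging and Classification of Sperm Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for off-axis digital holographic microscopy of
    sperm cells. Generates synthetic sperm-shaped phase objects under four
    condition classes (normal, cryopreserved, oxidative stress, ethanol),
    forward-models off-axis interferograms with coherent and partially
    spatially coherent noise regimes, recovers phase by Fourier-transform
    demodulation and Goldstein branch-cut unwrapping, applies image-retention
    quality control, and classifies condition classes with an 11-feature
    classical machine-learning path (SVM, naive Bayes, kNN) and a small
    convolutional neural network trained with stochastic gradient descent
    with momentum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    e1071,
    class,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
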