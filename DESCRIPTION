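Package: cryentropy
Title: Entropy-Based Acoustic Screening of Newborn Cries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end newborn cry diagnostic pipeline for two-class
    (healthy vs. septic) screening from segmented cry audio. Provides a
    framing/windowing front end for mono PCM WAV cry units, three cepstral
    feature sets (mel-frequency, spectral-entropy and spectral-centroid
    cepstral coefficients), a fuzzy-entropy feature-selection rule driven by
    one-dimensional fuzzy c-means clustering, K-nearest-neighbour and
    Gaussian-kernel support-vector classifiers tuned by Bayesian
    hyperparameter optimisation under stratified five-fold cross-validation,
    a confusion-matrix evaluation suite including the Matthews correlation
    coefficient, and a seeded generator of two-class harmonic-plus-noise cry
    surrogates for exercising the pipeline without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
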