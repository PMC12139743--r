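Package: ieegencode
Title: Encoding Models of Facial-Emotion Features in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for modelling high-frequency broadband (HFB,
    110-140 Hz) intracranial EEG responses to facial-emotion features of a
    naturalistic movie. Provides HFB amplitude extraction (notch, common
    average reference, band-pass plus Hilbert envelope, epoching, 400 Hz
    resampling, square-root transform, baseline z-scoring), time-lagged
    ridge encoding models of 48 facial-emotion feature timecourses with
    5-fold cross-validation and a single global regularizer, temporal-shuffle
    permutation tests and t-test group inference on prediction accuracy,
    fold-pooled absolute-weight analysis against age, and a synthetic-cohort
    generator with known ground-truth weights for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
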