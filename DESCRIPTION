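Package: irispipe
Title: Iris Recognition Pipeline with Wavelet-Compressed PCA Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end iris biometric verification pipeline: circular
    Hough transform segmentation of the pupil and limbic boundaries,
    Daugman rubber-sheet normalization to a fixed-size polar template,
    one-level discrete wavelet decomposition with LL sub-band selection,
    principal component analysis for template compression, and per-subject
    linear support vector machines for accept/reject verification with
    false-accept and false-reject rate reporting. Includes a synthetic
    eye-image generator with known ground-truth geometry so every stage is
    testable without access to a gated iris database.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
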