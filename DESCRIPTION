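Package: skelage
Title: Multifactorial Skeletal Age-at-Death Estimation with Deep
    Randomized Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating adult age-at-death from ordinal
    macroscopic skeletal traits. Implements a deep randomized neural
    network regressor (random ReLU layers with skip connections, analytic
    ridge output layers tuned by SVD-based leave-one-out PRESS), a
    residual-regression uncertainty model yielding truncated-Gaussian
    prediction intervals, ordinal trait preprocessing (laterality
    collapse, one-hot encoding, 1-nearest-neighbour Jaccard imputation),
    intra-observer concordance via Kendall's W, CAR-score feature ranking
    through sphering, a Monte Carlo cross-validation evaluation harness,
    a linear surrogate explanation model, and a synthetic skeletal-trait
    generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
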