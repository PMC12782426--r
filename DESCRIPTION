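Package: waveresponse
Title: Inference of Mechano-Chemical Response Functions in Collective Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns history-dependent linear response functions that link
    mechano-chemical inputs (ERK activity gradients, cell-density gradients and
    velocity curvature) to single-cell acceleration in migrating epithelial
    monolayers. Provides trajectory feature extraction (Savitzky-Golay temporal
    derivatives, local quadratic surface fits, Gaussian kernel density
    estimation of the cell-density field, FRET/CFP ratio imaging), lagged-design
    ridge regression with two-stage cross-validated regularization, per-cell
    heterogeneity analysis (cosine-similarity matrices, principal components,
    prediction-ranked subgroups), a one-dimensional spring-particle simulator of
    ERK-wave-driven tissue flow with instantaneous and time-derivative radius
    rules, synthetic data generators with known ground-truth kernels, and a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
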