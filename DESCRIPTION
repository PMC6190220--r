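Package: viscell
Title: Dynamical Modeling of Single-Cell Viscoelasticity from AFM
    Stress-Relaxation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the viscoelastic properties of single cells from
    atomic force microscope (AFM) stress-relaxation force curves using a
    generalized Maxwell model. The model order is determined from the
    Hankel-matrix determinant-ratio statistic applied to the differenced
    (impulse) response, the decoupled elasticity and viscosity parameters
    are extracted by separable nonlinear least squares, and the fitted
    parameter vectors are summarized by principal component analysis and
    classified with a two-hidden-layer backpropagation network. Includes a
    synthetic-data generator emulating published per-cell-type parameter
    populations for four cell lines (MCF-7, Neuro-2a, HEK-293, L-929), a
    zero-phase Butterworth smoother, and relaxation-phase segmentation of
    full indentation records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
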