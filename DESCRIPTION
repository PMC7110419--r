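Package: tesopt
Title: Unified Optimal Targeting for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning multi-electrode transcranial electrical
    stimulation (TES/tDCS) montages. Generates layered concentric-sphere
    head models, assembles and solves the tetrahedral P1 finite-element
    forward problem, builds the electric-field transfer matrix and the
    reciprocal EEG lead field, and implements a unified family of montage
    optimizers: least-squares and weighted least-squares closed forms,
    budget-constrained weighted least squares, constrained directional
    maximization with integral or elementwise non-ROI field bounds, and
    reciprocity-based closed forms with per-electrode current limits.
    Includes intensity and focality metrics and a sweep engine over the
    non-ROI field bound that exposes the intensity-focality trade-off and
    its critical points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    quadprog,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
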