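Package: eisoclem
Title: Correlative Cryo-Microscopy Registration and Membrane Coat Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for correlative cryo-fluorescence / cryo-electron tomography
    analysis of BAR-protein coats on eisosome membranes. Provides fiducial-based
    registration of fluorescence coordinates into electron-microscopy maps with
    leave-one-out accuracy estimation, focal-stack attachment scoring, grouped
    dose-symmetric tilt-scheme generation, spline-guided sub-volume extraction
    with 2D collapse, regularized-likelihood 2D classification constrained by
    in-plane angle priors, and membrane thickness and coat-curvature morphometry
    (band profiles, peak/dip mean-level widths, relative membrane thickness,
    least-squares circle fits, Welch comparisons). A synthetic-phantom module
    generates fiducial scenes, focal stacks and membrane tomograms with missing
    wedges and known ground truth, so the whole pipeline is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
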