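Package: imschemo
Title: Chemometric Preprocessing Evaluation and ROI Annotation for Imaging Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, model-based evaluation of imaging mass
    spectrometry (IMS) data processing. Pixel spectra are read from imzML or a
    tab-delimited pixel-spectrum matrix, preprocessed with variance-stabilizing
    transformations (log10, ln, sqrt) and per-spectrum normalizations (TIC,
    median, mean, RMS, maximum peak), explored by mean-centered image PCA, and
    segmented into anatomical regions of interest with region-based (Chan-Vese)
    active contours in PCA score space. Segmented classes feed OPLS-DA models
    whose seven-block cross-validated predictive ability (Q2Y) ranks the
    preprocessing methods. Includes variance-stabilization diagnostics
    (SD-vs-mean heteroscedasticity profiles, RSD, Hotelling T2 score-plot
    ellipses) and a synthetic cerebellum-like tissue phantom with known region
    geometry, gain artifacts and heteroscedastic noise for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    xml2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
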