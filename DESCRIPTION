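Package: guvquant
Title: Per-Vesicle Quantification of Gene Expression in Synthetic Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene expression in populations of giant
    unilamellar vesicles (GUVs, "synthetic cells") from multi-channel
    epifluorescence microscopy images, and for characterizing quorum-sensing
    reporter assays. Provides a synthetic microscopy image generator with
    exact per-vesicle ground truth, circular-Hough vesicle detection on a
    reference dye channel, per-vesicle diameter and background-corrected
    intensity measurement, expressing-fraction classification against a
    negative-control threshold, four-parameter logistic (Hill) dose-response
    fitting with inverse prediction of unknown acyl-homoserine-lactone
    titers from dilution series, photomask patterning fidelity scoring, and
    a reproducible file-based pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
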