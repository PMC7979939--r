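Package: thzmargin
Title: Terahertz Refractive-Index Mapping and Morphological Dilation for
    Tumour Margin Delineation
Version: 0.1.0
Authors@R: person("thzmargin", "developers", role = c("aut", "cre"),
    email = "thzmargin@example.org")
Description: Reconstructs per-pixel complex refractive index maps from
    reflection-mode terahertz time-domain spectra of tissue on a dielectric
    substrate by grid-search minimization of a log-magnitude objective,
    classifies pixels by refractive-index thresholding followed by a single
    contour-constrained morphological dilation, registers the result against
    a reference pathology mask (contouring, bicubic resizing, rotation search
    by Pearson correlation), and evaluates classifiers with ROC curves, AUC
    and the TPR-FPR criterion. Includes a forward-model phantom simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
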