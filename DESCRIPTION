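Package: synscale
Title: Quantification of Multiplicative Homeostatic Synaptic Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify homeostatic synaptic scaling from miniature
    excitatory postsynaptic current (mEPSC) recordings and from surface-AMPA-
    receptor immunofluorescence. Implements the rank-order scaling-factor
    statistic (per-cell subsampling, pooling, sorting, top-fraction exclusion,
    count matching and linear fitting), mEPSC event detection in voltage-clamp
    current traces, field-EPSP initial-slope measurement, and a fluorescent-
    puncta quantification pipeline (sum projection, Li minimum-cross-entropy
    thresholding, FFT band-pass filtering, h-watershed segmentation, particle
    analysis, Gaussian size classification and rank-order intensity analysis).
    Ships seedable synthetic-data generators for amplitude populations, current
    traces and punctum images with ground truth, so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
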