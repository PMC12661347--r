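Package: longca
Title: Longitudinal Two-Photon Calcium Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for longitudinal multi-plane two-photon calcium imaging:
    cross-day three-dimensional field alignment using plane-wise image
    cross-correlation and a linear-offset Gaussian fit of axial correlation
    profiles, cell-mask detection by adaptive thresholding, seeded component
    trace extraction with a rank-1 global background model, AR(1)
    calcium-transient deconvolution, SNR and spatial-consistency component
    screening, moving-percentile delta-F-over-F baselines, cross-session cell
    matching by linear sum assignment on an intersection-over-union cost,
    trial-aligned activity maps for virtual-reality T-maze behavior, and
    watershed particle counting for glial immunostain quantification. A
    ground-truthed synthetic-data generator produces imaging sessions,
    structural stacks, behavior logs, and histology images so that every
    stage of the pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
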