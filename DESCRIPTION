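Package: pyrcollin
Title: Pyramidal Neuron Orientation and Collinearity from Segmentation Label Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for histology cell-segmentation label
    masks of the hippocampal pyramidal layer. Measures each segmented neuron,
    removes four classes of false-positive segmentations (extracellular
    speckle, undersized glia-like objects, oversized merged objects by
    diameter or area), fits moment-matched ellipses to extract axial
    orientations, corrects orientations for the curvature of the pyramidal
    layer against a centerline (CoO = CorrA - UncO + 90 degrees), and
    aggregates corrected orientations into collinearity measures (mean
    angular deviation from perpendicular and axial circular variance).
    Subregions are compared with slide-level rank-based quantile
    normalization followed by a linear mixed model with case and slide
    random intercepts, a likelihood-ratio test, and Tukey-style single-step
    multiplicity-adjusted pairwise contrasts. Includes a ground-truthed
    synthetic scene generator (curved laminae of elongated cells with axial
    von Mises orientation noise plus planted contaminants) so every stage
    is testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    mgcv,
    lme4,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
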