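Package: spheroidseg
Title: Multistep Segmentation and Quantification of Tumor Spheroid Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image analysis for 3D spheroid cultures imaged by confocal
    immunofluorescence and phase-contrast microscopy. Implements a multistep
    cell segmentation routine (median denoising, contrast stretch, automatic
    histogram thresholding, dilation, distance-transform watershed splitting
    and particle size filtering) together with the simple-threshold baseline
    it improves upon; spheroid-level morphometry (section mask, ROI gating,
    rim/core partition, growth-area analysis of phase-contrast series); and
    summary quantification (rim-enrichment bookkeeping, condition-level
    fluorescence, marker-positive cell fractions, loading-control-normalized
    band densitometry). Ships a deterministic synthetic-scene generator with
    exact ground truth for validating every step, and a reproducible
    end-to-end pipeline entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    jsonlite,
    yaml,
    readr,
    mclust,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
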