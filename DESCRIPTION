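Package: zonemig
Title: Proliferation-Insensitive Exclusion-Zone Migration Assay Simulation
    and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the lineage-dye exclusion-zone cell migration assay.
    Provides an agent-based simulator of the assay (persistent random-walk
    motility, stochastic division with 2-fold dye dilution, first-order dye
    decay and neighbor dye transfer, treatment scenarios), a synthetic
    fluorescence micrograph renderer, and the image-quantification pipeline:
    circular ROI detection on the pre-migration image, rigid ROI-pair
    alignment onto the post-migration image, the relative-migration intensity
    statistic in dual-image, single-image and count-based modes, image
    cytometry for nucleus counting, dye retention and mixed-culture dye
    transfer, and a scenario runner with ANOVA-based group comparison. The
    dye-based statistic reads migration out as redistribution of the conserved
    parental fluorescence mass and is therefore insensitive to proliferation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    multcomp,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
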