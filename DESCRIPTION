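Package: screencall
Title: Hit Calling and Imaging Quantification for High-Content RNAi
    Viability Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide RNAi modifier screens read
    out by live/dead image cytometry. Converts per-well nuclei and
    propidium-iodide counts into survival fractions, computes
    library-referenced Z-statistics with per-run, per-plate or global
    scoping, and calls hits through a three-tier cascade: a Z-threshold
    primary rule, gene-annotation filtering, Dunnett many-to-one
    confirmation against a transfection control, and a specificity tier
    comparing alpha-synuclein-overexpressing against GFP-expressing cells
    with Welch t-tests under step-down Sidak adjustment. Statistical
    machinery (Dunnett and Tukey adjusted p-values by deterministic
    quadrature, Holm-Sidak, D'Agostino-Pearson normality) is implemented
    in the package. Companion imaging metrics cover thresholded Manders
    colocalization, line-profile area-under-curve partitioning,
    trans-Golgi-network morphology classification, neurite skeleton
    statistics, nuclear signal quantification and LDH kinetic rates.
    Synthetic-data generators with serialized ground truth make every
    stage testable without access to screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    pracma,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    mvtnorm,
    multcomp,
    withr
Config/testthat/edition: 3
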