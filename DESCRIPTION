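Package: fosmap
Title: Whole-Brain Light-Sheet c-Fos Quantification and Atlasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative whole-brain analysis of light-sheet
    fluorescence microscopy (LSFM) volumes of cleared mouse brains:
    iterative population-average template construction with hemisphere
    symmetrization, multi-regional transfer of hierarchical atlas
    annotations, dual-channel c-Fos positive cell detection with
    autofluorescence-based false-positive removal (cube-filter maxima,
    seeded watershed, size filtering), sphere-density heatmaps in atlas
    space, registration-quality metrics (deformation magnitude, regional
    intensity variance, landmark distances with Welch comparison), and
    per-region negative-binomial count statistics with Dunnett many-to-one
    contrasts, false-discovery-rate adjustment and influence diagnostics.
    Includes a synthetic phantom generator with known ground truth so the
    whole pipeline is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    mvtnorm,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
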