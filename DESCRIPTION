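Package: imcpheno
Title: Segmentation, Phenotyping and Spatial Analysis of Multiplexed
    Imaging Mass Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end single-cell analysis of multiplexed imaging mass
    cytometry (IMC) data: nuclear/membrane composite images, quantile
    thresholding, prominence-based maxima seeding and seeded watershed
    segmentation, per-cell marker quantification, log plus double z-score
    normalization, multi-restart K-means phenotyping with a one-vs-one
    differential-marker rule and rule-based cell-type annotation,
    nearest-neighbor tumor-microenvironment proximity statistics,
    sample-median differential-state testing with Benjamini-Hochberg
    adjustment, and serial-section metastatic-burden scoring.  Includes a
    synthetic multichannel-image generator with ground truth so the whole
    pipeline can be exercised and validated without raw acquisition data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
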