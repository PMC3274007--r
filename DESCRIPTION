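Package: forestseg
Title: Forest Cover Mapping by Image Segmentation and Segment-Based
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for preparing tree-species-level forest cover maps from
    high-resolution multiband imagery.  Implements multiresolution
    region-growing segmentation driven by scale, colour/shape and
    smoothness/compactness weights, Gaussian maximum-likelihood pixel
    classification, segment-based reclassification by majority rule,
    object-based classification on segment means, a 3x3 majority filter
    baseline, and cluster-sampled error-matrix accuracy assessment with
    Cohen's kappa.  Includes a synthetic landscape simulator that renders
    mosaics of irregular forest stands with class-specific four-band
    spectral signatures and shadow/gap speckle, so the whole pipeline can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
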