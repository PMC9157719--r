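Package: dtpradiomics
Title: Dual-Time-Point PET Radiomics Repeatability and Use-Case Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how FDG-PET radiomic features respond to tracer
    uptake time relative to their test-retest repeatability. Provides a
    synthetic dual-time-point, double-baseline PET study generator with
    known ground truth; SUV-threshold, percentage-of-SUVmax and
    contrast-based lesion delineation; fixed-bin-width and fixed-bin-number
    intensity discretization; a 49-feature radiomic panel (conventional,
    shape, histogram, GLCM, GLRLM, GLZLM and NGLDM classes) computed from
    first principles; and the statistical machinery (agreement ICC, paired
    Wilcoxon tests with Benjamini-Hochberg correction, uptake-time z
    scores) to classify each feature into dual-time-point, cross-sectional
    or discarded use cases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
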