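Package: niptcnv
Title: Microdeletion and Microduplication Calling from Shallow-Coverage
    Cell-Free DNA Sequencing
Version: 0.1.0
Authors@R:
    person("niptcnv", "developers", email = "niptcnv@example.org",
           role = c("aut", "cre"))
Description: Detection of fetal and maternal copy-number aberrations from
    low-coverage whole-genome sequencing of maternal plasma cell-free DNA
    (non-invasive prenatal testing, NIPT). Reads are counted in fixed-width
    genomic bins, normalized by LOESS GC correction, principal-component
    residualization against a euploid reference cohort, bin filtering and
    per-bin mean subtraction, then partitioned by circular binary
    segmentation; segments are classified as fetal or maternal
    deletions/duplications against fetal-fraction-scaled significance
    thresholds. Includes derivation of syndrome critical regions from
    labelled deletion records by iterative coverage-cutoff lowering, an
    in-silico spike-in evaluation engine over fetal-fraction and read-count
    grids, and a fully synthetic data generator so the complete pipeline
    runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    IRanges,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
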