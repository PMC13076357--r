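Package: methclock
Title: RRBS Epigenetic Clocks with Individual-Aware Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-methylation age clocks from reduced representation
    bisulphite sequencing (RRBS) count data. Reads Bismark-style coverage
    files, filters and imputes per-CpG methylation ratios, rank-normalises
    within samples, selects age-correlated sites, fits an elastic-net age
    model with alpha/lambda tuning, and validates it by
    leave-one-individual-out cross-validation so repeated samples of the
    same animal never leak across folds. Includes downstream analyses of
    longitudinal epigenetic age change, age-class contrasts, PCA, sex
    effects, and CpG island/shore and genic context annotation, plus a
    synthetic longitudinal cohort generator with known per-site ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
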