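Package: adeca
Title: Comparative Genomics of Paired Adenoma-Carcinoma Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired benign-malignant (adenoma-carcinoma)
    tumor exomes: regional classification of somatic mutations into
    lesion-common and lesion-specific classes, cancer cell fraction (CCF)
    estimation with purity/ploidy/copy-number adjustment, Dirichlet-process
    binomial-mixture clustering of mutations by cellular prevalence in
    one-sample and two-sample modes with fitness-peak sharpness comparison,
    preranked gene-set enrichment on CCF changes between lesions,
    exome-based microsatellite instability calling from read-length
    distributions, and six-class categorization of somatic copy-number
    changes across the adenoma-carcinoma sequence. Includes a synthetic
    paired-lesion data generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
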