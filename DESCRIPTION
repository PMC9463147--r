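Package: tumorith
Title: Intra-Tumor Heterogeneity Analysis for Colorectal Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for quantifying intra-tumor
    heterogeneity (ITH) in tumor cohorts from somatic mutation calls,
    copy-number segments and cell-type fraction profiles. Estimates cancer
    cell fractions from variant allele fractions under purity and local copy
    number, classifies mutations and copy-number events as clonal or
    subclonal, infers per-sample subclone compositions by one-dimensional
    Gaussian-mixture clustering, and summarizes clonal diversity with the
    Shannon index for both genetic and microenvironmental composition.
    Classifies metastatic seeding of primary-metastasis pairs as monoclonal
    or polyclonal via the Jaccard similarity index, fits cross-validated
    lasso biomarker signatures of ITH with variable entry-order reporting and
    cross-cohort evaluation, and provides cohort-level statistics: consensus
    molecular subtype voting, cytoband copy-number enrichment by Fisher
    exact tests, logistic models of metastatic potential and correlation
    matrices. A synthetic tumor-cohort generator with known clone trees,
    binomial read sampling and planted gene-ITH effects makes every stage
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    mclust,
    jsonlite,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
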