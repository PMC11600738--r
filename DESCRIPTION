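Package: bandscape
Title: Cytoband-Level Copy-Number Loss Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls per-sample copy-number status at cytoband resolution from
    gene-level GISTIC-thresholded calls, screens for co-occurrence and mutual
    exclusivity of a cytoband-loss anchor against mutations and other
    copy-number alterations with Fisher exact odds ratios, contrasts gene and
    protein expression between loss and diploid tumors, deconvolves bulk
    expression into cell-type fractions under a linear mixing model with a
    signature-matrix ensemble, screens binary genomic features against drug
    log-IC50 response with Glass' delta and point-biserial effect sizes and
    elastic-net ranking, and compares overall survival by Kaplan-Meier and
    log-rank statistics. Ships a synthetic-cohort generator reproducing the
    statistical structure each stage assumes, so the whole pipeline is
    testable offline, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr
Config/testthat/edition: 3
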