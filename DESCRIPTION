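Package: oscmir
Title: miRNA Expression Signatures for Oral Cancer Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for distinguishing oral squamous cell
    carcinoma (OSCC) epithelium from normal epithelium using miRNA
    expression profiles from small-RNA sequencing (read counts) or
    RT-qPCR (Ct values). Implements reference-sample normalization over a
    consistently detected miRNA panel, exclusion of red-blood-cell
    contamination markers, two-class differential expression with
    Benjamini-Hochberg FDR control and rank-product permutation tests,
    a seven-algorithm classifier family (compound covariate predictor and
    its Bayesian variant, diagonal linear discriminant analysis, nearest
    centroid, k-nearest neighbours, linear support vector machine) with
    feature selection and significance-threshold optimization embedded in
    leave-one-out cross-validation, ROC/AUC evaluation, and miRNA-target
    KEGG pathway enrichment with an empirical random-miRNA-set negative
    control filter. A synthetic-data module generates two-class count and
    Ct datasets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
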