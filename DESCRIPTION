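Package: armonize
Title: Ensemble Reconciliation of Multi-Method RNA-Seq Differential
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconciles heterogeneous differential-expression calls made
    by several RNA-Seq analysis methods on the same samples.  Builds a
    gene-by-method log2 fold-change matrix with an explicit missingness
    mask, decomposes the union of significant calls into Venn regions,
    fits an Alternating Regression Model (each method's profile serves in
    turn as response, the remaining methods as regressors, with
    significance-driven backward elimination), averages fitted profiles
    across rotations into a consensus profile, and selects a
    high-confidence coreset by Tukey boxplot/IQR fences.  A PCA-based
    alternative selection, pseudogene-to-parental-gene association from
    tabular alignment hits, biotype/gene-family decomposition utilities,
    and ground-truth synthetic data generators are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
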