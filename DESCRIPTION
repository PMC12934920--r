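Package: vocalpredict
Title: Neonatal Vocalization Sequence Structure and Gene-Expression
    Predictors of Social Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the structure of neonatal mouse
    ultrasonic-vocalization (USV) call sequences and brain gene-expression
    variability to post-pubertal social-interaction variability in a
    15q11-13 duplication model. Implements 13-type call classification
    from frequency contours, Poisson-based inter-call-interval sequence
    segmentation, n-gram Shannon entropy profiles (H0-H4), Markov
    transition models with chance-multiple display tiers, UMAP embedding
    and density clustering of acoustic features, delta-delta-Ct relative
    quantification with group and variance statistics, and Lasso
    predictor selection with AIC model choice, subsample stability
    counting and correlation validation. A synthetic-cohort generator
    with the same statistical structure makes every stage testable
    without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    uwot,
    car,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
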