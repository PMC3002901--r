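Package: crhnet
Title: Candidate-Gene Extraction and Network Inference for CRHR1 Time-Course
    Two-Color Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screening pipeline for two-color spotted-array time-course
    experiments on CRH-stimulated corticotrope cells: print-tip loess
    normalization of MA ratios, two-way ANOVA prefiltering with
    Benjamini-Hochberg FDR, wrapper feature selection of small gene subsets
    by a genetic algorithm, simulated annealing and greedy Wilks-Lambda
    forward selection around a maximum-likelihood (linear) discriminant
    scored by leave-one-out cross-validation, a random-forest baseline,
    frequency-rank consensus across repeated runs, and inference of
    gene-gene association structure by PCA and a shrinkage graphical
    Gaussian model with significance-filtered partial-correlation edges.
    Includes a synthetic-data generator that plants differential-expression
    profiles, dye-by-time interactions and sparse partial-correlation
    networks so that every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    randomForest,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
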