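Package: crossherit
Title: Inheritance of Gene Expression in Reciprocal Hybrid Crosses from
    Two-Colour Microarrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing gene-expression inheritance
    in reciprocal crosses between two lines (e.g. wild and domesticated
    Atlantic salmon) assayed on common-reference two-colour microarrays.
    Provides intensity flooring and within-array Lowess (MA) normalization,
    the positive-and-significant quality filter, annotation-based
    probe-to-gene collapsing by lowest p-value, Welch t and Welch ANOVA
    differential expression with Benjamini-Hochberg correction and
    Student-Newman-Keuls post-hoc contrasts, additivity/dominance
    (delta/alpha) classification of hybrid expression into additive, dominant
    and over-dominant modes, maternal/paternal/parental effect
    categorization, and one-on-group gene-set perturbation tests with
    essential-gene extraction. A synthetic experiment generator plants known
    inheritance modes and perturbed gene sets so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    grDevices,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Microarray, DifferentialExpression,
    GeneSetEnrichment, QualityControl
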