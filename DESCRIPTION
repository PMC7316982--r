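Package: mwaskit
Title: Metagenome-Wide Association Analysis for Case-Control Gut
    Microbiome Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of case-control shotgun-metagenomic
    cohorts: rarefaction, alpha/beta diversity with PCoA ordination and
    ANOSIM, Wilcoxon rank-sum differential abundance with
    Benjamini-Hochberg control, construction of metagenomic linkage
    groups (MLGs) from co-abundant marker genes with vote-based
    taxonomy assignment, SparCC compositional correlation networks with
    permutation pseudo p-values, Monte-Carlo PLS-DA stability feature
    selection, cross-validated classifier evaluation with bootstrap
    AUC intervals, species-metabolite Spearman association heatmaps,
    and the exact contingency, survival, and enrichment statistics used
    in preclinical (mouse-arm) follow-up. Includes a seeded synthetic
    cohort generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    survival,
    randomForest,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
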