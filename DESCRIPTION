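Package: FosConnectome
Title: Whole-Brain Fos Coactivation Networks, Modules, Hubs and Expression Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds whole-brain functional connectomes from regional Fos
    (immediate-early gene) cell counts: log10(x+1) normalisation, per-group
    region-by-region Pearson correlation, Euclidean-distance hierarchical
    clustering with a half-height dendrogram cut for module detection,
    correlation-thresholded graphs with degree, betweenness, participation
    coefficient and within-module degree z-score, dual-criterion hub
    identification, cholinergic-subsystem correlation analyses with two-way
    ANOVA and Tukey post hoc tests, and a brain-wide screen correlating
    baseline regional gene-expression density with the withdrawal-induced
    Fos log-fold change under Benjamini-Hochberg FDR control. Includes
    synthetic-data generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    yaml,
    car,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
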