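Package: fosnet
Title: Functional Connectivity Networks from Regional c-Fos Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds immediate-early-gene (c-Fos) functional connectivity
    networks from per-subject regional activity densities. Provides a
    per-region group-difference screen (one-way ANOVA with step-down
    Student-Newman-Keuls post hoc tests and a compact letter display),
    per-condition interregional Pearson coactivity matrices, module
    detection by hierarchical clustering of Euclidean distances between
    correlation profiles with a half-height dendrogram cut, signed edge
    thresholding at an absolute-correlation cutoff, and node metrics for
    small signed networks (a weight-based modified within-module degree
    score and the participation coefficient). Includes a seeded synthetic
    study generator with planted block-correlation structure for
    validation, plus GraphML/GEXF export of the resulting networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    pheatmap,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    xml2
Config/testthat/edition: 3
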