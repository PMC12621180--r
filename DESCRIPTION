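Package: endoCaNet
Title: Network Analysis of Endothelial Calcium Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing agonist-evoked calcium dynamics across
    endothelial cell sheets imaged en face. From per-cell F/F0 fluorescence
    traces and an integer-labelled cell mask the package detects and fits
    calcium transients (exponentially modified Gaussian model), builds the
    structural cell-adjacency network, identifies spatially clustered
    agonist-sensitive responder communities with permutation null models,
    quantifies betweenness and eigenvector-based (eigengap / local influence)
    centrality of responder groups, estimates how recent neighbour activity
    changes a cell's event probability with a case-control design and a
    temporal permutation null, summarises lagged cross-correlation between
    cell pairs, and classifies concentration-response encoding (frequency
    versus amplitude modulation). A synthetic-tissue simulator generates
    tessellated cell sheets, clustered sensitivity maps and neighbour-coupled
    stochastic transients with exported ground truth so every analysis stage
    is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    minpack.lm,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
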