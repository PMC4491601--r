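Package: tropnet
Title: Tropical Semiring Aggregation and Metric Embedding of Multiplex
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates groups of same-node weighted networks (multiplex
    layers, e.g. one functional connectome per subject) under the
    (min,+) tropical semiring, embeds them in a common metric space via
    metric closure (a generalization of all-pairs shortest paths), and
    compares embedded networks from different modalities (functional
    vs. structural connectivity) through a z-scored absolute-difference
    grid with hypersphere-based detection of discordant nodes. Includes
    construction of functional connectivity from regional time series
    via zero-lag correlation with Fisher Z variance stabilization and
    autocorrelation-corrected effective degrees of freedom, classical
    multidimensional scaling for exploratory visualization, a synthetic
    data generator with planted ground truth, and a command-line
    pipeline over labeled CSV matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'algebra.R'
    'aggregation.R'
    'synthgen.R'
    'comparison.R'
    'connectivity.R'
    'io.R'
    'cli.R'
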