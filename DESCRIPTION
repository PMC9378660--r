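Package: brainmapper
Title: Topological Shape Graphs and Transition Dynamics for Parcellated
    Brain Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the landscape of whole-brain activity
    configurations in parcellated functional MRI recordings using the
    topological data analysis Mapper algorithm. Builds shape graphs from
    frames-by-parcels matrices via a geodesic k-nearest-neighbour filter,
    overlapping two-dimensional binning and partial single-linkage
    clustering; characterises the graphs through degree, closeness
    centrality and hub detection; annotates nodes with resting-state
    network activation; propagates node labels to time frames and
    estimates censoring-aware discrete-time Markov chains of state
    transitions; and compares results against linearity-preserving null
    models (phase randomisation and first-order vector autoregression).
    A synthetic-data generator with a planted hub-mediated Markov state
    structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    xml2,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: TimeCourse, GraphAndNetwork, Network, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ParcellatedTimeSeries.R'
    'preprocess.R'
    'mapper.R'
    'graph-metrics.R'
    'annotation.R'
    'brainmapper-package.R'
    'transitions.R'
    'null-models.R'
    'reliability.R'
    'io.R'
    'pipeline.R'
    'synthetic.R'
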