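Package: dieloperon
Title: Merging Bacterial Operon Predictions Using Diel Expression Time Series
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enhances in-silico operon predictions for cyanobacteria (and other
    prokaryotes with strong daily expression rhythms) by merging adjacent
    predicted operons whose genes share similar diel expression signatures.
    Implements the ABLIM (Area Between Linear Interpolations of Measurements)
    distance between expression time series, a four-statistic featurization of
    gene groups (minimum, mean, standard deviation and maximum of pairwise
    ABLIM distances), a cross-validated classifier registry including a
    logistic model tree, rule-based discovery of merge candidates from gene
    adjacency and strand, and a synthetic diel-genome generator with planted
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
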