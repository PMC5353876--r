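Package: tscnet
Title: Conserved Network Modules from Time-Series Expression and Protein Interactions
Version: 0.1.0
Authors@R: person("tscnet", "developers", email = "tscnet@example.org",
    role = c("aut", "cre"))
Description: Identifies a structurally conserved, context-shifting gene
    network module from time-series gene expression integrated with
    protein-protein interactions. Genes are scored per time point by their
    deviation from their own temporal mean (perturbation score), grouped
    into phenotype stages, thresholded at a data-derived mean +/- k sd band,
    and joined to a PPI scaffold to build stage-specific networks. The edges
    conserved across all stages form the common network, whose mean absolute
    score shift between two stages (delta-P) is tested against a resampling
    null that draws random same-sized stage networks from the pooled
    observed edges. Includes a synthetic-data generator with a planted
    drifting module, file readers/writers for expression tables (plain TSV
    and GEO series-matrix dialect), edge lists, gene lists and grouping
    configs, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
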