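Package: rhizotrn
Title: Transcriptional Regulatory Network Inference from Motif-Scan Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bacterial transcriptional regulatory networks (TRNs) from
    position-weight-matrix clustering output and stratified motif-scan hit
    tables, as used for multi-replicon rhizobial genomes. Implements the
    three-tier stringency target search that assigns each target gene to the
    strictest p-value stratum in which any transcription factor hits it,
    reconstruction of the network hierarchy by ascendant-edge removal and
    topological layering, a suite of thirteen normalized structural
    properties with Erdos-Renyi null ensembles for cross-network comparison,
    maximum-likelihood fitting of degree distributions to exponential,
    power-law and truncated power-law families ranked by Kolmogorov-Smirnov
    distance, and genome-context analyses (regulon annotation by COG
    category, neighbor-gene group detection, module cross-tabulation). A
    seeded synthetic-data generator produces genomes, motif matrices, planted
    regulons and scan-hit tables so the whole pipeline can be exercised and
    validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
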