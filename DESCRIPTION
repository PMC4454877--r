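Package: streamnet
Title: Co-Occurrence Networks and Beta Diversity for Stream Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for 16S amplicon OTU count tables from
    temporary (intermittent) headwater streams and similar systems:
    rarefaction and low-abundance filtering, Bray-Curtis dissimilarity,
    principal coordinate analysis, ANOSIM permutation tests, shared-OTU
    (Venn) partitioning, Chao1 richness, and Spearman co-occurrence
    networks validated against an Erdos-Renyi null ensemble with
    centrality-based keystone-taxon ranking. Includes a synthetic
    community generator with planted group structure and co-occurrence
    blocks so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    mclust,
    biomformat,
    optparse
Config/testthat/edition: 3
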