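Package: motifclust
Title: Motif Clustering Analysis of Directed Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how network motifs such as the feed-forward
    loop (FFL) aggregate in directed networks. Detects induced motif
    occurrences, computes the motif clustering coefficient and its
    homologous and heterologous variants, enumerates the catalog of pairwise
    motif clustering types (12 for FFL pairs), classifies motif pairs,
    derives per-node motif clustering diversity (MCD) and node spin, and
    assesses significance against null models (Erdos-Renyi, duplication
    growth, motif-count-preserving rejection sampling, degree-preserving
    randomization), including edge-removal robustness and group-size
    adjusted label-enrichment statistics.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
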