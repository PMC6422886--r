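Package: dmsc
Title: Dynamic Multi-Seeds Clustering of 16S rRNA Amplicons into OTUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bins 16S rRNA amplicon reads into operational taxonomic units
    (OTUs) with a dynamic multi-seeds greedy clustering algorithm. Instead of
    a single seed, each sufficiently large cluster is represented by a set of
    multi-core sequences (MCS) - a clique of members whose pairwise alignment
    distances all fall below the clustering threshold - and new reads are
    admitted either by their average distance to the MCS or by its deviation
    from the within-MCS mean relative to the MCS distance standard deviation.
    The MCS is updated dynamically as clusters grow, and isolated reads are
    rescued into their nearest cluster at the end. Includes exact pairwise
    global alignment distances (banded, with provably exact adaptive bands),
    clustering evaluation metrics (NMI and pair-based MCC), a labelled
    amplicon community simulator for offline benchmarking, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
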