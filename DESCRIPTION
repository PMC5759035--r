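Package: cbcsyncom
Title: Community-Based Culture Collection Deconvolution and Synthetic
    Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing community-based culture collections (CBCs)
    of plant-associated bacteria: deconvolution of multi-member culture
    wells from long-amplicon 16S consensus reads into well-level (wOTU) and
    collection-level (cOTU) operational taxonomic units via greedy centroid
    clustering; k-mer bootstrap taxonomy assignment; cross-referencing of
    cultured OTUs against a culture-independent microbiome profile to
    estimate core-microbiome recovery; abundance-ranked synthetic community
    (SynCom) design by greedy well set cover; short-read amplicon profiling
    with expected-error, length and plastid filters; and colonization
    statistics (Bray-Curtis, PCoA, ANOSIM, Kruskal-Wallis, displacement
    summaries) for inoculated versus uninoculated plants. Ships a fully
    seeded synthetic-data generator with a ground-truth manifest so the
    entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
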