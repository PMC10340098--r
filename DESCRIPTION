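Package: netDR
Title: Network-Neighborhood Drug Repositioning from Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate drugs for a disease by comparing the network
    neighborhood of drug-perturbed genes with the neighborhood of
    disease-associated genes on a weighted functional interaction network.
    Differentially expressed genes from drug-treatment signatures and from
    a disease cohort are mapped to the network as direct-neighbor modules;
    module genes are scored with z-score-adapted Adamic-Adar, damped
    PageRank and neighborhood-scoring metrics; and each drug receives a
    bidirectional combined AUC measuring how well one module's ranking
    recovers the other's membership. Includes a synthetic-data generator
    that emulates the statistical structure of the real inputs (sparse
    weighted interactome, heavy-tailed drug z-scores, planted disease
    modules and signature-reversing drugs) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
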