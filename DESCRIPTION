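Package: calpainGRN
Title: Gene-Regulatory Network Dissection of Post-Translational Protease Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify direct and indirect targets of a
    post-translationally acting protease (a plant calpain such as DEK1) from
    multi-genotype time-course expression data. Implements GENIE3-style signed
    gene-regulatory network inference with tree ensembles, subnetwork detection
    and regulator-hierarchy analysis via local reaching centrality, spline-based
    likelihood-ratio time-course differential expression with misregulation
    profile classification, network enrichment analysis tests (NEAT) under a
    hypergeometric null, N-degron (N-end rule) classification of predicted
    protease cleavage sites, upstream regulon tracing, and factorial
    differential gene expression network enrichment analysis (FDGENEA) mapping
    binary phenotypic traits to regulatory subgraphs. Ships a synthetic-data
    generator with known ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    igraph,
    ranger,
    mclust,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
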