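Package: refugia
Title: Mitochondrial Phylogeography: Haplotype Networks, Demographic
    Inference and Coalescent ABC Model Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-locus mitochondrial phylogeography:
    reading aligned mtDNA sequences and sample metadata, collapsing sequences
    into haplotypes, building minimum-spanning haplotype networks with latent
    intermediate nodes, computing diversity indices (segregating sites,
    nucleotide and haplotype diversity, private haplotypes) with a rarefaction
    procedure, fitting the sudden-demographic-expansion mismatch model
    (tau, theta0, theta1) with parametric-bootstrap goodness of fit, Tajima's D
    and Fu's Fs neutrality tests with coalescent p-values, a seeded structured
    coalescent simulator for three-population divergence scenarios, and
    Approximate Bayesian Computation scenario choice by weighted multinomial
    logistic regression with local-linear parameter estimation. A seeded
    synthetic-data generator emulates star-like expansion clusters, two-refuge
    disjunct structure and bimodal co-distributed subclusters so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
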