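Package: micronet
Title: Network-Based Genetic Association Analysis of Latent Micronutrient Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking a latent micronutrient phenotype to
    genetic variation through a metabolic/protein-interaction network. Builds a
    latent metabolite phenotype by principal component analysis of repeated
    assessments, applies genotype quality control (call quality, completeness,
    minor allele frequency, exact Hardy-Weinberg test), fits per-SNP generalized
    estimating equations with sibling-cluster sandwich errors, aggregates SNP
    p-values to gene level with a linkage-disequilibrium-aware Monte-Carlo null,
    partitions the interaction network into topological modules by spin-glass
    simulated annealing, tests modules and QTL-window gene sets for
    hypergeometric enrichment, and screens plasma proteins by robust regression.
    Includes a synthetic-cohort generator (sibling clusters, LD-block genotypes,
    a planted latent factor, and a modular network with planted enrichment) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    igraph,
    MASS,
    sandwich,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    fgsea,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
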