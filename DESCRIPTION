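Package: trianet
Title: Network-Based Inference of Population Substructure for Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers population substructure in case/control genotype panels by
    building a social-network-style graph of individuals. Each individual is
    grouped with its two rank-closest partners (by genetic covariance) into a
    triad; the triads are merged into a graph whose unconnected components and
    Louvain communities serve as discrete ancestry covariates in per-SNP
    logistic-regression association tests. Includes Price-style genotype
    normalization and principal components as a comparator, standard data
    cleaning (minor-allele-frequency filtering, linkage-disequilibrium pruning,
    long-range-LD region exclusion), a Balding-Nichols simulator of stratified
    and admixed case/control studies, and an experiment grid that measures
    type-I error and power of each correction strategy on random,
    differentiated and causal test SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
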