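Package: HaploGeo
Title: Phylogeographic Analysis of Haploid Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic and historical-demography analysis of
    aligned haploid (typically mitochondrial) sequence data sampled across
    geographically structured locations. Provides within-sample diversity
    statistics (haplotype and nucleotide diversity with Nei's variances),
    hierarchical analysis of molecular variance (AMOVA) with Phi-statistics
    and permutation tests, pairwise Hudson FST and island-model gene-flow
    estimates, Mantel tests for isolation by distance, median-joining
    haplotype networks, mismatch-distribution analysis under the
    sudden-expansion model with parametric-bootstrap goodness of fit,
    Harpending's raggedness index, Fu's FS neutrality test with coalescent
    null distributions, and a structured-coalescent simulator with HKY+I
    mutation for generating study-scale synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
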