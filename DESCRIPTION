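Package: cogselect
Title: Ortholog Family Detection and Codon-Model Tests of Selection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for comparative molecular-evolution
    analysis of gene families. Detects orthologous groups across genomes
    by reciprocal-best-hit (COG-style) clustering with paralog collapsing
    and triangle merging, builds neighbor-joining phylogenies from JTT
    maximum-likelihood protein distances with bootstrap support, and
    tests for shifts in selective pressure with Goldman-Yang (GY94)
    codon substitution models: branch-specific dN/dS ratios, branch-site
    mixture models of positive selection with likelihood ratio tests and
    Bayes empirical Bayes site posteriors, and pairwise dN/dS estimation
    with synonymous-saturation filtering. Includes a codon and genome
    simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
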