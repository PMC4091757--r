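Package: mirCons
Title: Cross-Species Conservation Analysis of Disease-Associated MicroRNAs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies animal mature microRNAs that are 100% identical to
    human disease-associated microRNAs, quantifies precursor (hairpin)
    conservation by progressive multiple alignment, pairwise divergence
    proportions (p-distance) and Neighbor-Joining phylogenies, filters
    miRNA-target orthologs by reciprocal percent identity, and integrates
    the results into a 28-field animal disease-miRNA resource table. A
    synthetic-data generator evolves miRNA families along a fixed species
    tree under a uniform point-substitution model with known ground truth,
    so every stage of the pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'mirCons-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'align.R'
    'conservation.R'
    'homolog-match.R'
    'mirna-io.R'
    'nj.R'
    'ortholog.R'
    'resource.R'
    'simulate.R'
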