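Package: motifcons
Title: Phylogenetic Conservation Analysis of RNA-Binding Protein Recognition Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the evolutionary conservation of degenerate
    RNA-binding-protein recognition elements (such as the Puf-family UGUA
    motifs) in 3' UTRs across a phylogeny. Implements degenerate-motif
    scanning and joint position permutation, a Fastcompare-style pairwise
    ortholog co-occurrence test with a permuted-motif empirical null, a
    branch-length-weighted conservation score with permutation-based false
    discovery rates, mutual-information-driven discovery of anchored 10mers
    with iterative masking and ROC-slope cutoffs, enrichment statistics
    (Fisher, binomial sign, rank-sum, sequence-context preference), and
    binding-site dependence models (stepwise logistic regression and
    four-state single-step Markov gain/loss models fit by MCMC with Bayes
    factors). A synthetic-data module simulates trees, binding-site
    histories and UTR sequences so the whole pipeline can be exercised and
    validated without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
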