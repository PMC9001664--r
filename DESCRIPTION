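Package: tcrclonics
Title: Single-Cell TCR Repertoire Clonality, Convergence and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of paired-chain single-cell T cell receptor (TCR)
    repertoires from 10x Genomics V(D)J contig annotations or AIRR
    rearrangement tables. Calls clonotypes from productive alpha/beta
    chain pairs, detects expanded clones, and quantifies clonality and
    diversity (Gini index, Shannon entropy, CDR3 spectratype, power-law
    fits of the clone-size distribution). Quantifies clonotype sharing
    across samples, classifies longitudinal clone dynamics between
    paired timepoints, groups convergent CDR3 sequences into motif-based
    specificity groups with resampling-based k-mer enrichment, and tests
    the coupling between clonal structure and a per-cell transcriptome
    embedding (permutation coherence tests, sequence-distance versus
    embedding-distance correlation, k-nearest-neighbour batch-mixing
    entropy). Includes a synthetic cohort generator with ground truth
    for power-law clone sizes, chain dropout, planted CDR3 motifs,
    clone-correlated embeddings and paired pre/post timepoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
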