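Package: htselex
Title: Enrichment Analysis and Simulation for High-Throughput SELEX
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing high-throughput sequencing data from SELEX
    aptamer selections. Raw per-round FASTQ reads are trimmed to their
    fixed-length random-region cores, counted, and summarised into per-round
    unique-sequence statistics and molecular-enrichment folds. Aptamer
    families are grouped by primary-sequence edit distance together with
    predicted secondary-structure similarity (base-pair maximisation
    folding), and each family's round-to-round fate is classified.
    Dissociation constants are estimated from concentration-response
    binding data by one-site saturation nonlinear regression. A synthetic
    SELEX experiment generator provides ground-truth libraries with
    compositional bias, spiked biased sequences, affinity-weighted
    selection, and PCR-method-dependent amplification bias (solution PCR
    versus droplet digital PCR), so that every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
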