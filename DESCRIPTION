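Package: introdrop
Title: Detecting Alien Introgressions from Exome-Capture Coverage Drops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting alien chromosome
    segments (introgressions and deletions) in a hexaploid crop genome from
    exome-capture sequence coverage. Provides a synthetic cohort generator
    (reference, diverged donor genomes, mosaic accessions, gradient-placed
    capture probes, genotype matrices), a divergence-dependent capture and
    paired-end read simulator, a seed-and-extend unique-mapping read
    aligner, zero-inclusive binned coverage with cohort-relative drop
    calling, genotype-similarity clustering (UPGMA), in-silico probe
    efficacy scoring, global-alignment indel diagnosis, and donor
    attribution of unmapped reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
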