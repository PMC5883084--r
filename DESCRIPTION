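Package: schic3d
Title: Single-Cell Hi-C Contact Processing and 3D Genome Structure
    Calculation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for evaluating single-cell Hi-C
    experiments. Processes paired-end reads into filtered, non-redundant
    chromatin contacts (ligation-junction clipping, unique mapping,
    restriction-fragment assignment, molecular-event filters, read-pair
    support and promiscuity filtering) with full quality-control
    accounting; summarises contacts as genome-wide maps and
    contact-probability versus sequence-separation curves with polymer
    reference slopes; computes whole-genome 3D structures from contacts by
    hierarchical simulated annealing of a particle-on-a-string chromosome
    model; and quantifies model precision by iterative weighted-SVD
    superposition and all-particle RMSD. A synthetic-data generator
    produces genomes, ground-truth conformations, contacts and raw read
    pairs with known labels so every pipeline stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tools,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
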