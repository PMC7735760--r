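Package: samosa
Title: Single-Molecule Adenine-Methylated Oligonucleosome Footprinting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule chromatin fibre footprinting data in
    which accessible adenines are exogenously methylated (m6dA) and detected
    through elevated interpulse durations (IPD) during single-molecule
    real-time sequencing. Converts per-base kinetics into per-molecule
    posterior probabilities of adenine methylation with a two-component
    Gaussian mixture on robustly normalized log-IPDs, calls nucleosome dyads
    and nucleosome repeat lengths (NRL) on single molecules, computes
    single-molecule autocorrelograms and clusters fibres into oligonucleosome
    patterns with Leiden community detection, and performs feature-centric
    enrichment analyses (strand-aware motif windows, MNase-cut profiles,
    Fisher exact tests with Storey q-values). Includes a synthetic kinetics
    simulator with known nucleosome positions so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
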