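Package: optscaf
Title: Optical-Map-Guided Scaffold Validation, Super-Scaffolding and
    Pseudomolecule Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates genome sequence scaffolds against Bionano-style
    optical label maps, detects and splits chimeric scaffolds at N-gaps,
    orders and orients scaffolds along map contigs with optically
    estimated gap sizes, and anchors the resulting super-scaffolds into
    chromosome pseudomolecules using genetic-map markers.  Includes
    in-silico digestion for direct-label and nicking chemistries, a
    dynamic-programming label-map aligner with a sizing-error model,
    CMAP/XMAP/AGP readers and writers, assembly statistics, and a
    simulator that generates genomes, scaffold sets, noisy optical maps
    and linkage maps with machine-readable ground truth.
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
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
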