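Package: sweeppower
Title: Power of Selective-Sweep Scans in Bottlenecked Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent simulation of hard selective sweeps under severe
    bottleneck demographies, together with the two classical genome-scan
    statistics used to detect them: a SweepFinder-style composite likelihood
    ratio built on the background site frequency spectrum, and the omega
    statistic built on linkage disequilibrium. Includes neutral-null threshold
    calibration, true/false-positive classification against a known sweep
    target, and Monte-Carlo power studies over demographic and selection
    parameter grids. Haplotype samples are exchanged in Hudson ms text format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
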