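Package: repstress
Title: Analysis of Experimental Evolution Under DNA Replication Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the computational analyses used in
    yeast experimental-evolution studies of DNA replication stress:
    Poisson-based convergence testing of recurrently mutated genes with
    multiple-testing control and background filtering, selection-coefficient
    estimation from fluorescent-reference competition assays, copy-number
    profiling from 100-bp binned read depth, replication-timing (t_rep)
    inference with origin and termination calling and fork-velocity
    estimation, chi-square enrichment of chromosomal features in fork-stall
    zones, allele-frequency trajectories from Sanger peak heights, and
    cell-cycle summary metrics from DNA-content histograms. A synthetic-data
    module generates ground-truth-labelled inputs for every stage so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
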