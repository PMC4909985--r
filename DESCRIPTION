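Package: mosaicX
Title: Detection and Characterization of Mosaic Chromosome X Alterations
    from SNP Array Intensity Data
Version: 0.1.0
Authors@R:
    person("mosaicX", "Developers", email = "mosaicx@example.org",
           role = c("aut", "cre"))
Description: Detects large (>2 Mb) mosaic structural events on the female X
    chromosome from SNP-array B-allele frequency (BAF) and log R ratio (LRR)
    data.  Implements circular binary segmentation of mirrored BAF over
    informative probes, Gaussian-mixture typing of BAF bands, copy-state
    assignment from batch-adjusted LRR, and closed-form mosaic cell-fraction
    estimation for losses, gains and copy-neutral events.  Companion modules
    phase detected events to the inactive or active X using promoter
    methylation beta values, call relative X copy number from qPCR standard
    curves, and compute cohort-level statistics (Wilson intervals, exact
    binomial tests, odds ratios, logistic regression).  A synthetic-data
    generator produces SNP-array, methylation and qPCR inputs with known
    ground truth so the full pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
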