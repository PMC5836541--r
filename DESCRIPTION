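Package: pfseq
Title: Pooled Fitness Profiling by Barcode Sequencing Under Periodic Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale analysis of relative proliferation rates
    (fitness) of pooled barcoded deletion mutants competing through serial
    dilution in steady and periodically fluctuating environments. Includes a
    forward simulator of BAR-Seq competition experiments with known ground
    truth, error-correcting demultiplexing of Hamming-coded sample indices and
    Levenshtein-tolerant barcode mapping, count filtering and normalization,
    relative fitness estimation against an artificial wild-type reference, the
    time-average (homogenization) null and its negative-binomial GLM test with
    an environmental-change covariate, genetic-variance decomposition with
    bootstrap confidence intervals, antagonistic-pleiotropy and transgressive-
    fitness calling with permutation nulls, and flow-cytometry competition
    analysis with density gating and automatic GFP thresholding.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
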