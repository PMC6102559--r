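Package: codelcall
Title: 1p/19q Co-Deletion Calling from MLPA Probe Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies diffuse gliomas by 1p/19q copy-number status from
    multiplex ligation-dependent probe amplification (MLPA) probe ratios
    using a three-region majority rule that separates complete whole-arm
    co-deletion from isolated segmental 1p deletion, alongside two
    published all-loci and per-arm-majority criteria. Includes raw
    peak-table normalization, a sequencing peak-height mutation caller with
    multi-assay IDH consensus integration, concordance statistics (weighted
    Cohen's kappa, exact and chi-square association tests, locus
    correlation), a truth-labelled synthetic cohort simulator for
    purity-scaled hemizygous losses with FFPE artifact loci, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
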