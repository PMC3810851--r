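Package: zimpute
Title: Direct Imputation of GWAS Summary-Statistic Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Imputes association Z-scores at unmeasured variants directly
    from measured-variant Z-scores and linkage-disequilibrium correlations
    estimated in a phased reference haplotype panel, using the conditional
    expectation formula for multivariate normal variates under the null
    hypothesis. Works on a sliding scheme of prediction windows nested in
    larger extended windows, harmonizes summary statistics to the panel's
    allele orientation, and reports a per-variant imputation quality score.
    Includes a seeded quantitative-trait simulation subsystem (mosaic
    haplotype panel with block-wise LD, causal-variant phenotypes,
    single-variant regression Z-scores, missing-at-random masking) for
    evaluating imputation accuracy end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
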