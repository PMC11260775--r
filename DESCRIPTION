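Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-sample Mendelian randomization
    (MR) with GWAS summary statistics: genome-wide significant instrument
    selection with greedy linkage-disequilibrium clumping against a local
    reference panel, proxy-SNP substitution for instruments missing from
    the outcome study, allele harmonization with strand-flip resolution
    and frequency-based inference for palindromic variants, four causal
    estimators (random-effects inverse-variance weighted, MR-Egger,
    weighted median, weighted mode), heterogeneity and pleiotropy
    diagnostics (Cochran's Q, Egger intercept, MR-PRESSO global, outlier
    and distortion tests), leave-one-out and trait-category exclusion
    sensitivity analyses, instrument-strength and asymptotic power
    calculations for binary outcomes, and a seeded synthetic-data
    generator with known causal truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
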