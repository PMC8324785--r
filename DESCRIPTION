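Package: aggmeta
Title: Sample-Overlap-Aware Multivariate GWAS Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate genome-wide association meta-analysis (GWAMA) for
    strata with overlapping samples, as arises when the same children are
    phenotyped by several raters, instruments and ages within a cohort.
    Builds the expected cross-trait-intercept matrix from observed sample
    overlap and phenotypic correlations, combines per-stratum Z scores into
    an overlap-corrected multivariate test statistic with an effective
    sample size, enforces stratum admission and age-binning rules, and
    provides a minimal LD-score-regression toolkit (SNP-heritability,
    intercept, genetic correlation with a heritability Z-score gate).
    Includes a multi-cohort, multi-rater synthetic-data generator for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
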