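Package: mrpipe
Title: Two-Sample Mendelian Randomization with Pleiotropy-Gated Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: reading and harmonizing exposure and outcome
    association records, instrument selection (genome-wide significance,
    greedy LD/distance clumping, explained variance and F-statistic
    filtering), six causal-effect estimators (Wald ratio, inverse-variance
    weighted, maximum likelihood, MR-Egger, weighted median, penalized
    weighted median), MR-PRESSO outlier detection and correction,
    heterogeneity- and pleiotropy-gated model selection, cross-cohort
    inverse-variance meta-analysis with Bonferroni significance tiers, and a
    synthetic summary-statistics generator with known ground truth for
    calibration and parameter-recovery testing. All user-facing functions
    take data frames and return tibbles.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
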