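Package: mrmediate
Title: Two-Sample Mendelian Randomization Mediation Analysis with an
    Observational Triangulation Arm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for two-sample Mendelian randomization
    (MR) mediation analysis: instrument selection (genome-wide significance
    filtering, greedy LD clumping, outcome-association exclusion, F-statistic
    screening), allele harmonization, univariable MR estimators (inverse
    variance weighted, MR-Egger, weighted median, weighted mode) with the full
    sensitivity suite (Cochran's Q, Egger intercept, leave-one-out,
    MR-PRESSO-style outlier detection, sample-overlap bias approximation),
    multivariable MR including an L1-penalized variant, and product/difference
    mediation decomposition with proportions mediated. A survey-weighted
    observational arm (design-based logistic and linear regression, subgroup
    interaction tests, Rubin's-rules pooling) triangulates the MR findings.
    Synthetic GWAS summary statistics and survey populations are generated from
    an explicit structural model so the whole stack is testable end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
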