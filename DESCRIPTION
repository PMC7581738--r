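Package: fractalrest
Title: Long-Range Temporal Correlations and Variance of BOLD Time Series in
    Rest-Task-Rest Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detrended fluctuation analysis (DFA) of regional brain time
    series with Hurst-exponent estimation, signal variance, fit-quality
    gating, and paired nonparametric session contrasts with false discovery
    rate control, as used in rest-task-rest resting-state fMRI studies.
    Includes an exact fractional Gaussian noise simulator (circulant
    embedding) so full multi-subject, multi-session studies with known
    ground truth can be generated and the whole pipeline validated by
    parameter recovery. All user-facing functions take and return tibbles.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
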