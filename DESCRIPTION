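Package: lfpextract
Title: Automatic Feature Extraction from Evoked Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects latency and amplitude features of stimulus-evoked local
    field potentials (LFPs): the first maximum, the response onset, the
    inflection point, and the main negative peak. First and second
    time-derivatives of each noisy sweep are estimated by Phillips-Tikhonov
    regularization with the regularization parameter tuned by the discrepancy
    criterion, so that zero-crossing based detection is robust against the
    noise amplification inherent in numerical differentiation. Includes a
    parametric generator of noiseless LFP templates with analytic ground
    truth, a Monte Carlo study of estimation error as a function of
    signal-to-noise ratio, batch processing of multi-sweep recordings stored
    as delimited text, and ggplot2 diagnostics.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
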