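Package: rsnec
Title: Resting-State Network Entropy-Connectivity Coupling Analysis
Version: 0.1.0
Authors@R:
    person("RSNEC", "Developers", email = "rsnec@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling between resting-state network
    (RSN) functional connectivity and BOLD signal temporal regularity.
    Implements wavelet-based regularity analysis (stationary wavelet
    transform, BayesShrink-informed tolerance, lagged-pattern sample
    entropy with motion-aware pattern exclusion), RSN-level reduction of
    ROI functional-connectivity matrices with principal component
    analysis, an elastic-net model linking network entropies to the
    primary connectivity component, group-difference and interaction
    statistics, and a synthetic cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
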