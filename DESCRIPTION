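Package: elascape
Title: Energy-Landscape Analysis of Binarized Multichannel Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multichannel time series by exact-enumeration moment matching, builds the
    resulting energy landscape (local minima, basins of attraction,
    disconnectivity graph with energy barriers), classifies landscape minima
    into two major brain states and a minor class, and quantifies brain-state
    dynamics per subject (appearance frequency, direct and indirect
    major-state transitions, dwell times). Includes Metropolis random-walk
    simulation on fitted landscapes, Welch group comparisons and clinical
    score correlations of the dynamic indices, and a synthetic-cohort
    generator with group-specific landscape depth for end-to-end validation
    when restricted clinical data are unavailable.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
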