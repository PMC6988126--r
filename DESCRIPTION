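Package: loopscape
Title: Chromosome Conformation Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, masks and balances Hi-C contact matrices, computes
    observed/expected transforms and contact-probability curves, quantifies
    A/B compartments, calls punctate long-range interactions with a
    donut-filter (HiCCUPs-style) local background, performs aggregate peak
    and aggregate TAD analysis with shifted-region controls, normalizes
    Capture-C viewpoint profiles (percent reads per promoter), calibrates
    count tables with exogenous-genome spike-ins, and estimates single-cell
    DNA-FISH contact probabilities with a calibration-derived distance
    threshold. A first-class synthetic-data module plants compartments,
    TADs, focal loops, distal Capture-C peaks, contact/background distance
    mixtures and spike-in mixing ratios with known ground truth, so every
    stage of the pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
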