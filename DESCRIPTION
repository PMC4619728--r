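Package: gazenet
Title: Network Analysis of Face-Scanning Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing how viewers scan faces
    with an eye tracker. Detects fixations from raw 60 Hz binocular gaze
    samples with a velocity-threshold (I-VT) classifier, labels them against
    rectangular areas of interest (AOIs) expanded by a configurable visual
    angle, computes classical fixation-time metrics (per-AOI percentages and
    a left/right eye ratio), and builds per-participant AOI transition
    networks from which a standardized weighted degree centrality (0-100) is
    derived for each facial feature. Includes the group-level inferential
    layer (ANCOVA with mental-age covariates, one-sample t-tests, Pearson
    correlations and Fisher r-to-z comparison of independent correlations)
    and a seeded Markov scanpath simulator so the whole pipeline can be
    exercised and validated on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
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
    tidyr,
    utils,
    withr
Suggests:
    car,
    igraph,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
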