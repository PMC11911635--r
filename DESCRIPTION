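Package: phenocage
Title: Behavioral Phenotyping of Home-Cage and Maze Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deep behavioral phenotyping of mice from automated
    tracking data. Segments continuous home-cage traces into movement,
    arrest, shelter-visit and activity-bout events; derives per-animal
    behavioral thresholds from Gaussian mixture models fitted to
    log2-transformed event statistics; computes a 20-parameter registry of
    spontaneous behavior including habituation and light/dark-switch
    indices; scores maze and object tasks (discrimination indices,
    alternation, probe-trial quadrant metrics, freezing, serial-reversal
    learning curves); and applies a normality-gated statistical ladder with
    chance-level tests, false-discovery-rate correction and a wild-type
    pooling consistency filter. A seeded synthetic-behavior generator with
    exact ground truth makes every stage testable without raw videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
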