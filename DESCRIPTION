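Package: trapvote
Title: Plurality Consensus for Citizen-Science Camera-Trap Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning crowd-sourced camera-trap image classifications
    into one consensus record per capture event. Implements the streaming
    retirement rules used to pull image sets out of circulation (blank,
    blank-consensus, consensus, complete), a plurality voting algorithm with
    median species richness, ordinal count-bin medians, behaviour proportions
    and Pielou-evenness certainty scores, validation against expert
    gold-standard labels (mismatch taxonomy, per-species accuracy, count-bin
    agreement), a seeded volunteer simulator with per-species confusion and
    blank-when-unsure behaviour, and export of search effort and
    species-specific detection histories for occupancy and relative-abundance
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    vegan,
    withr
Config/testthat/edition: 3
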