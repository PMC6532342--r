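Package: searchmatch
Title: Single-Target Match-3 Visual Search Task Generation and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building and scoring an experimentally controlled
    match-3 visual search task. Provides match-3 board mechanics (run
    detection, swap legality, match resolution with gravity and
    deterministic refill), enumeration and symmetry classification of the
    16 three-tile target patterns, a factorial difficulty-level space over
    board width, height and number of tile types, a constrained generator
    of playable trials in which every board holds exactly one valid move,
    a plain-text trial file format with a replay validator, a headless
    session engine that emits move-level logs, performance metrics (search
    time, Tukey-fence outlier filtering, processing time per item, search
    slope), and a synthetic-player simulator with known ground-truth
    effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
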