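Package: emaphase
Title: Attractor Phases, Instability and Change Mechanisms in Daily Diary Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Idiographic (N-of-1) analysis of day-level ecological momentary
    assessment diaries of challenging behavior in residential care. Detects
    stable phases in binary incident series by recursive partitioning with
    minimum-duration and minimum-change constraints, pairs change-points
    across behavior series into attractor transitions, labels attractor
    states and summarises per-phase salience of hypothesized risk and
    protective factors, screens contemporaneous and lag-1 factor-behavior
    associations with exact tests, quantifies instability as windowed
    dynamic complexity (fluctuation times distribution) with a one-tailed
    z threshold, classifies transitions as event- and/or instability-induced,
    and ships a synthetic single-case generator with known ground truth so
    the whole pipeline can be validated without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
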