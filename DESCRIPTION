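Package: larvaquant
Title: Quantification of Drosophila Larval Escape Behavior and
    Stimulation-Locked Calcium Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying optogenetically evoked escape
    responses of Drosophila larvae from tracked spine kinematics.
    Computes Choreography-style per-frame features (speed, crabspeed,
    curvature, head angle, body length, bias) from Multi-Worm-Tracker
    style spine tables, classifies frames into an ethogram
    (roll/crawl/turn/hunch/stop/backup) with transparent rules,
    segments behavior bouts, and derives per-larva and population
    escape metrics: rolling probability with confidence intervals,
    bout durations, first-roll onset/offset latencies, and
    roll-to-crawl transition timing. Includes the contingency-table
    and rank-based statistics used in this literature (Pearson
    chi-square, Mann-Whitney U with exact small-sample enumeration,
    Kruskal-Wallis, Bonferroni correction, Cohen's d, Wilson score
    intervals), stimulation-locked dF/F analysis of ROI calcium
    traces with dose-response summarization, and a ground-truthed
    synthetic larva and GCaMP simulator so every stage is testable
    without raw tracking data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
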