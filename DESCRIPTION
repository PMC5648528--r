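Package: flysleepr
Title: Sleep Scoring, Homeostasis and Circadian Analysis for Drosophila Locomotor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing Drosophila sleep and circadian behaviour from
    locomotor recordings. Reads TriKinetics Drosophila Activity Monitor (DAM)
    files and video-derived position traces, scores sleep with the standard
    5-minute immobility rule, computes per-phase sleep metrics (duration, bout
    structure, latency, waking activity), quantifies sleep-deprivation
    efficiency and hourly cumulative sleep rebound against a clock-matched
    baseline, estimates free-running period with the chi-square (Sokolove-
    Bushell) periodogram, and performs the group comparisons used in
    behavioural phenotyping (one-way ANOVA with Holm-Sidak-corrected pairwise
    t tests). A two-state wake/sleep simulator with circadian drive and a
    homeostatic pressure variable generates realistic synthetic cohorts,
    including mechanical sleep-deprivation protocols, so every analysis stage
    can be exercised and validated without raw recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
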