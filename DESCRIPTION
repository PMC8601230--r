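Package: caosc
Title: Automated Analysis of Egg-Activation Calcium Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ratiometric (Fura-2 F340/F380) calcium
    time series recorded from activated mammalian eggs. Provides robust
    per-trace baseline estimation, threshold-based calcium transient
    detection with hysteresis-style offsets, extraction of the standard
    per-egg metric panel (latency to the first transient, first-transient
    duration, oscillation counts and frequency, area under the curve,
    and oscillation persistence with censoring), exact and asymptotic
    Mann-Whitney U tests, the Mantel-Cox log-rank test, and a seeded
    synthetic-trace generator with ground truth for validating every
    stage of the pipeline, including type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
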