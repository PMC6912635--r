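Package: circaclock
Title: Circadian Locomotor Activity Analysis for DAM Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing circadian locomotor activity recorded with
    TriKinetics Drosophila Activity Monitors (DAM2). Reads and writes the
    32-channel DAM2 monitor format, applies an automated dead-animal filter,
    classifies individuals as rhythmic with the Sokolove-Bushell chi-square
    periodogram and estimates the free-running period (tau) under constant
    darkness, extracts daily activity-profile phase markers (onset, peak,
    offset) in Zeitgeber time under light-dark cycles, and fits cohort-level
    statistics (random-intercept mixed models with isofemale line nested in
    location, likelihood-ratio tests, binomial GLMs for rhythmicity
    proportions, latitudinal cline summaries). Includes a synthetic-data
    generator that simulates per-minute Poisson beam-cross counts from
    parametric activity waveforms under entrainment and free-run, with
    built-in presets for southern and northern Nasonia vitripennis
    populations, so the whole pipeline can be validated by planted-parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
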