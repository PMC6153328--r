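Package: vmradapt
Title: Explicit and Implicit Learning Analysis for Visuomotor Rotation Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for center-out visuomotor rotation experiments
    with verbal aiming reports. Converts 100 Hz reach trajectories into hand
    angle, reaction time and movement time, decomposes adaptation into explicit
    (reported aim) and implicit (hand minus aim) components, applies the
    +/- 3 SD outlier screen, and provides the full between-group statistics
    battery: one-way and 2x3 Type-III factorial ANOVA from raw data or printed
    (n, mean, sd) summaries, Tukey-Kramer post-hoc tests, pooled t-tests with
    Cohen's d and Hedges' g, JZS default Bayes factors, and noncentral-t power
    analysis. Includes a synthetic-cohort simulator (two-process explicit plus
    implicit state-space learner) of the 7-block, 8-target, -45 degree rotation
    protocol so the whole pipeline can be exercised without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    car
Config/testthat/edition: 3
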