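Package: jumptrack
Title: Simulation and Analysis of Eye-Hand Coordination in a Target-Jump
    Interception Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rapid eye-hand coordination in a manual
    interception task in which a target falling down a screen can suddenly
    jump sideways. Provides the task geometry and trial scheduling, a
    synthetic-cohort generator with known ground truth (participant-specific
    latencies, main-sequence kinematics, measurement noise, blinks and
    preemptive movements), zero-phase Butterworth preprocessing, saccade
    detection by a velocity criterion, extrapolation-based hand reaction
    times, interception geometry, hyperbolic main-sequence fits and movement
    vigor, and the condition-level statistics used in this paradigm
    (condition medians, two-by-three repeated-measures ANOVA with Bonferroni
    post hocs, trial-by-trial linear mixed models and correlations).
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
    lme4,
    lmerTest,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
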