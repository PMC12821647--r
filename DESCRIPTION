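Package: gazeload
Title: Eye-Gaze and Self-Report Metrics for Cognitive Load Evaluation in Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for evaluating driver cognitive load from
    remote eye tracking (60 Hz head pose and gaze rays) and NASA-TLX self
    reports. Projects per-frame gaze rays onto a head-anchored mobile
    reference plane, segments the trajectory into fixations, saccades and
    blinks with threshold-based rules, computes windowed gaze metrics
    (fixation duration, saccade velocity, blink number, stationary gaze
    entropy, gaze transition entropy) with window- and participant-level
    quality control, scores the adjusted NASA-TLX, and quantifies how well
    each measure discriminates driving stages of differing load via
    expected-direction accuracy, Spearman correlation and Lin's concordance
    coherence. Includes a seeded synthetic-cohort generator with ground-truth
    oculomotor events for validation, since study datasets of this kind are
    typically not public.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
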