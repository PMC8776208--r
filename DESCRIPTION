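Package: hrvstress
Title: Within-Subject Trends in Nightly Heart Rate Variability and Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for studying within-subject associations between
    wearable-derived nocturnal heart rate variability (HRV) and longitudinal
    mental-health outcomes. Turns per-night inter-beat-interval series into
    nightly RMSSD via artifact screening and five-minute segmentation, builds
    per-participant daily tables with a calendar-aware seven-day rolling
    standard deviation of lnRMSSD (HRVsd), estimates per-window linear trend
    betas between five-weekly questionnaires, scores the Four-Dimensional
    Symptom Questionnaire (4DSQ) with change scores and floor-effect
    screening, and fits a three-step moderated hierarchical regression with
    simple-slope (buffering) profiles. A synthetic-cohort generator with
    configurable latent trends and effect sizes makes every stage testable
    without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    sandwich
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
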