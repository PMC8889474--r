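Package: vrcue
Title: Eye-Metric Extraction and Analysis for Virtual-Reality Nicotine
    Cue-Exposure Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-tracking logs recorded during virtual-reality
    (VR) nicotine cue-exposure sessions: blink detection from runs of missing
    pupil-diameter samples (with noise and microsleep discard rules), per-object
    gaze fixation-time accounting by cue category, attentional-bias indices,
    per-category pupillometry, in-task visual-analogue-scale survey aggregation,
    and the paired-samples effect-size statistics (Cohen's d_z with
    normal-approximation confidence intervals) used to contrast Active
    (nicotine-cue) against Neutral scenes. A seeded synthetic-session simulator
    generates session logs with known ground truth (category-biased gaze dwell,
    cue-evoked pupil shifts, blinks, tracker dropouts, microsleeps) so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
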