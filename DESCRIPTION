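Package: tardicasa
Title: Computer-Assisted Sperm Analysis for Tardigrade Spermatozoa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinematic and waveform analysis of swimming tardigrade
    spermatozoa from digitised midline traces: arc-length station
    resampling, body-frame waveform normalisation, signed-curvature
    profiling of the head and tail filaments, curvilinear velocity (VCL),
    beat-frequency estimation by peak counting, straight-versus-turn
    motion classification, and per-station variance-ratio significance
    profiles. Includes a seeded synthetic flagellar-beat generator with
    known ground truth for end-to-end parameter-recovery testing, plain
    text trace/track input and output, and an experiment driver that runs
    the full simulate-analyse-report pipeline on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
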