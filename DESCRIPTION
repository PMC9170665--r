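Package: osarir
Title: Headless Task Engine, Race-Model Simulator and Analysis for
    Anticipated Response Inhibition (OSARI) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A headless, fully testable implementation of the logic of the
    OSARI anticipated response inhibition task: session and block
    construction, trial scheduling, the adaptive 1-up/1-down stop-signal
    delay staircase, feedback classification, and stimulus-position
    arithmetic, without any graphics or timing hardware.  Includes an
    independent horse-race participant simulator for generating realistic
    sessions, bit-exact readers and writers for the OSARI and STOP-IT
    trial-level '.txt' formats, and a batch analysis suite producing go and
    stop descriptives, inhibition functions, integration-method stop-signal
    reaction time (SSRT) estimates and proactive-inhibition measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
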