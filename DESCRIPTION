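Package: sonimotion
Title: Movement Sonification Pipelines for Animal-Computer Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning animal object-manipulation into sound. Implements
    a wired strain pipeline (four piezoelectric channels summed on a
    microcontroller, noise gating, a two-stage thrust detector with a 5 ms
    confirmation delay and a 300 ms refractory period, ASCII serial parsing)
    and a wireless motion pipeline (3-axis accelerometer deltas, Euclidean-norm
    jerk, activation thresholding with a continuously reset debounce timer),
    together with the drop-test linear calibration analysis, onset-aligned
    strain-type profiling with per-bin Welch tests, configurable
    event-to-sound mappings with pluggable playback sinks, parameter-stamped
    CSV session logs, seeded synthetic signal generators for hardware-free
    testing, and summarisation of coded behavioral annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
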