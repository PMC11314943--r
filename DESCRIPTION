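Package: bedradar
Title: Multi-Radar Sleep Posture Estimation with Spatial Radar Echo Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for impulse-radio ultra-wideband (IR-UWB) radar based
    sleep posture monitoring. Simulates multi-radar range-profile frames of a
    body lying on a bed, suppresses static clutter by slow-time mean
    subtraction, projects each radar's one-dimensional range profile onto a
    shared two-dimensional bed grid (a Spatial Radar Echo Map), classifies
    sleep postures with a multiview convolutional network trained on the map
    stacks, and runs a sensor-placement ablation protocol over a registry of
    radar subset configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
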