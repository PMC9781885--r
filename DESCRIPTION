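Package: mpezones
Title: Minute-by-Minute Intensity Zones from Metabolic Power Events in Soccer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing soccer players' in-game energy expenditure at
    one-minute resolution from GPS wearable exports. Fuses a metabolic-power-event
    (MPE) stream with 5-minute aggregate energetic metrics into a 25-feature
    per-minute table, clusters minutes into low/middle/high intensity zones with
    min-max normalisation, PCA and K-means (elbow-selected k), compares per-game
    load variability against conventional whole-game speed-band metrics via the
    coefficient of variation, and estimates per-player Markov intensity-transition
    matrices with a fitness-tracking index. Includes a regime-switching synthetic
    game simulator with known ground truth so the whole pipeline is testable
    without proprietary vendor data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
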