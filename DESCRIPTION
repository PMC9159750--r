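Package: mtobjmotion
Title: Detection of Scene-Relative Object Motion from Depth-Cue Conflict in Area MT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how macaque middle temporal (MT)
    neurons support detection of objects that move relative to the scene during
    observer self-motion. Implements the cue-conflict stimulus geometry (depth
    from binocular disparity versus motion parallax around a pedestal depth),
    depth-sign tuning indices with permutation tests, ideal-observer ROC metrics
    (neurometric performance and detection probability), psychometric and
    logistic choice-regression analyses of behavior, and a correlated-noise
    pseudo-population linear decoding simulation. A synthetic MT population
    generator provides trial-level neural and behavioral data with the
    statistical structure the analyses assume, so the full pipeline runs and is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
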