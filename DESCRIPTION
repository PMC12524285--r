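Package: satsn
Title: Spatial-Adaptive Two-Stream Detection of Giraffe Daily Behaviors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated detection of daily behaviors (licking,
    standing, walking, eating) of giraffes in fixed-camera zoo video. The
    package implements a spatial-adaptive two-stream network (SATSN) with a
    tubelet-token vision-transformer slow pathway, a temporal-attention fast
    pathway and stage-wise lateral fusion; keypoint-guided mouth-region input
    routing; observation-centric multi-object tracking (Kalman re-update
    along virtual trajectories, momentum association cost, recovery pass);
    AVA-format and detection-stream readers and writers; frame-level
    detection metrics (precision, recall, F1, average precision, mAP,
    confusion matrices) and ethogram time-budget statistics; and a seeded
    synthetic multi-agent scene generator so the full pipeline is testable
    without any video download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
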