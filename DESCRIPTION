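Package: ethokit
Title: Behavioral Kinematics of a Rodent Gap-Jumping Distance-Estimation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for landmark pose tracks from a rodent gap-jumping
    (distance estimation) task: DeepLabCut-dialect CSV input/output, confidence
    filtering and calibration, decision-period head and eye kinematics, segmentation
    of discrete head movements at velocity zero crossings with PCA plus k-means motif
    clustering, pupil-ellipse gaze analysis (vergence, head-eye cross-correlation),
    sticky autoregressive hidden Markov model behavioral states with linear
    discriminant decoding of experimental condition against fold-wise shuffle nulls,
    and a fully seeded synthetic pose-data generator with ground-truth bookkeeping
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
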