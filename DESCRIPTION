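Package: gaitkit
Title: Multi-Cattle Gait Kinematics and Lameness Classification from Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Downstream analysis of animal pose estimation for dairy-cattle
    mobility scoring. Reads per-frame 15-keypoint pose annotations, tracks
    individual cows across frames with a SORT-style Kalman/Hungarian tracker,
    extracts per-frame back-posture and head-carriage kinematics (back-line
    regression RMSE, topline area sections, signed head and nose elevation,
    neck angle), aggregates them into per-cow summary statistics, screens
    features against mobility scores with Pearson correlation and Kendall's
    coefficient of concordance, and classifies lameness under four label
    schemes with gradient-boosted trees, repeated-holdout cross-validation,
    recursive feature elimination, and chance-corrected agreement statistics.
    Includes a synthetic gait simulator so the full pipeline can be exercised
    and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    clue,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
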