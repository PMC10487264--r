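Package: neosort
Title: Multi-Object Tracking and Mobility Quantification for Penned Broilers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the mobility of broiler chickens from
    top-down pen video detections. Implements a deep-sort-style online
    tracker (constant-velocity Kalman filter plus Hungarian assignment),
    a post-hoc lost-ID/new-ID re-association algorithm that repairs
    occlusion-induced identity switches by positional distance threshold
    (neo-deep sort), bounding-box centroid extraction with pixel-to-cm
    calibration, fixed-interval resampling with a deadband displacement
    filter, and per-bird and flock-level distance, speed and appearance
    summaries. Includes a pen simulator that generates ground-truth
    trajectories and realistically corrupted detection streams
    (occlusion dropouts, miss-detections, false positives, box jitter)
    so the full pipeline can be validated without video, plus detection
    metrics (precision, average precision, R squared) and MOT-Challenge
    and YOLO label file readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    yaml,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
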