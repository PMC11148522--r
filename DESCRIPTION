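Package: flms
Title: Prediction Ranking for Small Longitudinal Multimodal Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a prediction-ranking framework for small, sparse,
    longitudinal, multimodal passive-sensing panels. Enumerates all nonempty
    sensor-modality fusions, runs a pluggable regression suite under four
    cross-validation strategies spanning user-agnostic (leave-one-participant-out,
    leave-time-unit-out) and personalized (accumulated-time-unit forecasting,
    leave-one-time-unit-of-participant-out) modeling, selects per-participant best
    models by minimum absolute sum error, aggregates prediction tensors across
    fusion combinations, encodes week-over-week change to binary labels, ranks
    candidate tensors by hamming distance to ground truth, and fuses the four
    strategies through a distance-weighted ensemble. Includes a synthetic-cohort
    generator with latent autoregressive symptom trajectories and PHQ-9-like
    weekly scores, per-user evaluation metrics, and experiment harnesses
    comparing the framework against singular strategies and leave-one-out
    classical baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    rpart,
    class,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
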