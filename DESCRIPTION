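Package: gazeskill
Title: Laparoscopic Skill Classification from Gaze Time Series and Task Video
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for objective assessment of laparoscopic peg-transfer skill.
    Trials are scored from task duration and dropped-peg penalties, grouped into
    novice/intermediate/expert levels by one-dimensional k-means, and classified
    by two branches: a shapelet transform of the gaze coordinate time series fed
    to a stacked heterogeneous ensemble (seven base learners with a logistic
    regression meta-learner or majority voting), and a small convolutional
    network over class-balanced task frames. Branch probabilities are fused by
    an extreme learning machine. Includes a seed-controlled synthetic-data
    generator with planted class structure, repeated-run evaluation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    jpeg
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
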