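Package: scanbin
Title: Spatiotemporal Binning and Expertise Classification of Eye-Tracking Scanpaths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-fixation scanpaths recorded while experts
    and trainees inspect images. Implements a discretized spatiotemporal
    encoding in which each trial's fixations are split into temporal groups and
    counted within spatial grid cells, yielding a fixed-length count vector per
    trial; the curated set of five classic gaze features (scan time, fixation
    count, regressive fixations, saccade path length, coverage of salient image
    area); a two-class synthetic scanpath generator; and a stratified
    cross-validation benchmarking harness comparing encoded against traditional
    features across Gaussian process, logistic regression, k-nearest-neighbour
    and gradient-boosting classifiers with optional PCA/kernel-PCA reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    class,
    kernlab,
    glmnet,
    xgboost,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
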