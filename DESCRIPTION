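Package: clamrfo
Title: Chaotic Levy Adaptive Manta Ray Foraging Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Continuous and binary optimization with CLA-MRFO, a Manta Ray
    Foraging Optimization variant augmented with chaotic control variables
    (circle, logistic and tent maps), Levy-flight sampling, hybrid population
    initialization, a three-bank elite memory archive, adaptive multi-strategy
    local search, and stagnation-triggered partial restarts. Includes a
    shifted-rotated benchmark-function factory with a baseline MRFO
    implementation and nonparametric comparison statistics (Friedman, Nemenyi,
    Wilcoxon), a binary wrapper feature-selection mode with leakage-free
    nested cross-validation for two-class gene-expression classification, and
    a synthetic expression-data generator for testing the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
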