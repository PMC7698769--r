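Package: cropscout
Title: Autonomous Aerial Crop Scouting by Spatial Ensemble Extrapolation
    and Nearest-Neighbour Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale simulator and analysis library for fully
    autonomous aerial crop scouting. An unmanned aerial system (UAS)
    samples a fraction of a gridded crop field, extrapolates a complete
    crop-health map with an ensemble of eight directional neighbour
    predictors and a prediction-window fill algorithm, and chooses flight
    actions with a k-nearest-neighbour reinforcement-learning rule.
    Includes excess-green (ExG) vegetation-index health labelling, a
    seedable synthetic corn-field generator, local-feature and random
    scouting baselines, a battery/recharge mission model, map-accuracy
    metrics, and a cost-benefit and nutrient-runoff assessment module.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, png
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
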