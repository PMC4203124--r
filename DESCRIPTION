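Package: headcast
Title: QTL-Based Ecophysiological Prediction of Wheat Heading Date
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Day-step ecophysiological simulation of heading date in bread
    wheat (Triticum aestivum L.) from daily temperature and photoperiod, with
    thermal-time accumulation modulated by vernalization and photoperiod
    response functions. Includes brute-force grid calibration of the genotype
    parameters V_sat (vernalization requirement), P_base (photoperiod
    sensitivity) and TT_emhe (earliness per se) against multi-environment
    heading observations, standardized-regression-coefficient sensitivity
    analysis, structure-corrected marker-trait association with permutation
    adjustment, backward-elimination marker models that predict the genotype
    parameters from allelic classes, bundled reference marker models, a
    seeded synthetic-data generator, and an end-to-end
    calibrate/fit/predict/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
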