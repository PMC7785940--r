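Package: phytomedia
Title: Design, Neurofuzzy Modeling, and Optimization of Plant Tissue Culture Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven design of plant tissue culture mineral media.
    Converts salt recipes (mg/L) to ion profiles (mM) via a versioned salt
    registry, generates D-optimal factorial designs over multiplier-scaled
    salt groups with a Fedorov exchange algorithm, fits parsimonious additive
    tensor B-spline (neurofuzzy) models of morpho-physiological shoot
    responses with structural-risk-minimization model selection and extracts
    fuzzy IF-THEN rules with membership degrees, trains per-response
    multilayer perceptrons with resilient backpropagation, and searches the
    design space with a desirability-weighted genetic algorithm. Includes
    validation statistics (Welch tests from printed summaries, ANOVA with
    Tukey HSD, Kruskal-Wallis) and a synthetic-experiment generator with the
    vessel/explant replicate structure of micropropagation trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
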