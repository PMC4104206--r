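Package: dyadRecip
Title: Stationary and Dynamical Reciprocity in Directed Social Event Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing reciprocity in temporal, directed networks of
    social events recorded by intermittent interviews, such as hosting of
    drinking or food-sharing events among the families of a small village.
    Provides an observation-windowed panel container for hosting and
    observability indicators built on SummarizedExperiment; pedigree-based
    relatedness and spherical household distances; a crossed-random-effects
    logistic regression of daily hosting with AIC model selection, permutation
    significance and variance-explained accounting; a windowing-corrected
    conditional-probability estimator of short-timescale ("conditional-action")
    reciprocity tested against a three-level hierarchy of stationary null
    models with Monte-Carlo significance; and a synthetic village-and-events
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
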