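Package: segconn
Title: Resting-State Network Segregation and Moderated Brain-Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying functional brain network segregation from
    resting-state node time series and relating it to spoken language
    production across adulthood. Implements sphere-node parcellations on an
    MNI reference grid, Fisher-z connectivity matrices with negative-edge
    thresholding, within-/between-network connectivity and per-network and
    whole-brain segregation, language production measures (verbal fluency
    scoring, picture-naming reaction time, mean length of utterance, moving
    average type-token ratio) and their z-score composite, and moderated
    regression with Cook's-distance influence screening and Johnson-Neyman
    regions of significance on the age scale. A seeded synthetic-cohort
    generator with block-correlated node time series and a planted moderated
    linear model makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
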