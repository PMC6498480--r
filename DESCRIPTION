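Package: recistvar
Title: Impact of Measurement Variability on RECIST Response Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how radiologic measurement variability propagates into
    RECIST-based trial endpoints. Fits a bivariate hierarchical
    measurement-error model on square-root-transformed repeated lesion
    readings, derives intra- and inter-reader error distributions, simulates
    hypothetical second assessments to build probability tables of response
    and progression designation, and evaluates any trial dataset by producing
    95 percent central ranges of the reassessed objective response rate and
    progression rate, together with coverage-based validation procedures and
    a simulation-study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
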