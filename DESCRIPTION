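Package: pdst
Title: Pesticide Decision Support Tool for Ranking Aquatic Risk of Active Ingredients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks pesticide active ingredients by their potential risk to
    freshwater ecosystems receiving agricultural runoff. The aquatic risk score
    is the product of a measure of effect (maximum application rate in umol/ha
    divided by an ecotoxicity threshold in umol/ML) and a measure of mobility
    and persistence (soil half-life x water half-life x the proportion of the
    applied ingredient transported in runoff, predicted from the organic
    carbon-water partition coefficient). Includes a threshold-derivation engine
    based on species sensitivity distributions (log-logistic and Burr III) with
    an assessment-factor fallback, support for band and spot spray regimes and
    tank mixes, rank-based sensitivity diagnostics, and a bundled reference
    dataset of 47 active ingredients registered for sugar cane and its rotation
    crops in Queensland, Australia.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
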