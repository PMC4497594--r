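Package: mobflow
Title: Gravity and Radiation Models for Regional Mobility Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying regional human mobility from daily-location
    diaries of the kind produced by mobile-phone call detail records, and for
    fitting and systematically evaluating spatial interaction models on the
    resulting origin-destination flow tables. Implements trip extraction with
    majority-tower daily location assignment, duration stratification of
    trips, Euclidean / road-network / least-cost travel-time distance
    measures, Poisson-regression gravity models (unconstrained, production-,
    attraction- and doubly constrained via iterative proportional fitting),
    the parameter-free radiation model with a fitted traveler fraction, and a
    diagnostic suite (log-ratio errors, deviance reduction, Sorensen-Dice
    agreement, exclusion of unmodelable routes, and a logistic model-choice
    regression on the gravity factor). A synthetic-data module generates
    districts, flows, subscriber diaries and friction rasters with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
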