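Package: adbmweb
Title: Food Web Prediction with the Allometric Diet Breadth Model and
    Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts food web structure from species body masses with the
    allometric diet breadth model (ADBM), an optimal-foraging (contingency
    model) predictor of consumer diets, and estimates its parameters and food
    web connectance by rejection approximate Bayesian computation (ABC) with
    an Epanechnikov acceptance kernel and the true skill statistic (TSS) as
    the measure of fit. Includes readers and writers for delimited community
    and predation-matrix files, structural food web properties with
    standardized prediction errors, and seeded synthetic benchmarks
    (log-uniform body-mass communities, model-generated ground-truth webs,
    random link deletion emulating under-sampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
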