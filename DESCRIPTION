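Package: dendromix
Title: Growth, Climate, and Insect Epidemics in Mixed Boreal Stands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dendroecological analysis pipeline for basal area increment
    (BAI) chronologies of black spruce and trembling aspen in pure and mixed
    boreal stands. Builds mean BAI chronologies from ring-width series
    (Tucson/.rwl and long-form CSV), computes crossdating statistics,
    bootstrapped climate-growth correlation functions, insect-epidemic
    intensity covariates, and fits a six-coefficient Bayesian linear model
    per chronology by Metropolis-Hastings sampling with uniform coefficient
    priors and a Jeffreys prior on the residual scale. Parameters are
    compared across chronologies with a posterior overlapping-coefficient
    rule. A synthetic-data generator with known ground truth emulates the
    tree-ring and monthly climate inputs so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
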