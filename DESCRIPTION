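Package: hooftrim
Title: Economic Evaluation of Dairy-Herd Hoof-Trimming Strategies for Sole Ulcers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markov cohort model comparing targeted partial-herd hoof
    trimming every two months against whole-herd hoof trimming every six
    months for the management of sole ulcers in dairy cows. Computes
    discounted three-year costs, benefits and the between-strategy
    difference in net benefits; runs a probabilistic sensitivity analysis
    with Beta-distributed probabilities and Normal-distributed prices, a
    deterministic one-way (tornado) sensitivity analysis, and scenario
    analyses over trim-targeting and herd size. A per-cow stochastic
    microsimulation with the identical event structure serves as a
    brute-force validation oracle for the cohort expectations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr (>= 3.0.0)
Config/testthat/edition: 3
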