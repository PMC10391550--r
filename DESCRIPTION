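Package: corticotroph
Title: Spike and Burst Analysis of Pituitary Corticotroph Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the electrical excitability of anterior
    pituitary corticotrophs from current-clamp membrane-potential recordings.
    Provides threshold-based event detection with spike versus pseudo-plateau
    burst classification, afterhyperpolarization-based A/B cell phenotyping,
    twelve-parameter per-cell summaries with correlation-filtered principal
    component analysis, exact and parametric cohort statistics (Fisher's
    exact test, Welch's t-test), a minimal conductance-based model
    corticotroph, and a software BK-channel dynamic clamp (first-order
    activation kinetics integrated by forward Euler) for closed-loop
    conductance-injection experiments. A synthetic-trace generator produces
    labelled recordings and cohorts for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
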