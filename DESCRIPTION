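Package: fluxspan
Title: Constraint-Based Modeling of Oxidative Stress Effects on Gut Microbe
    and Host Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of metabolic networks under
    oxidative stress, centred on the flux-span-ratio (FSr) statistic for
    comparing flux variability between a reference ("healthy") and a
    perturbed ("disease") model. Provides a tidy metabolic-model container
    with TSV, JSON and SBML readers and writers; flux balance analysis,
    flux variability analysis and minimum-norm flux distributions over a
    built-in bounded-variable simplex; quality-controlled model expansion
    with reactive-oxygen-species reaction sets and automated
    blocked-reaction debugging via demand and sink additions; iMAT-style
    context-specific model extraction from categorical protein-expression
    evidence by mixed-integer programming; host-microbe community model
    pairing through a shared lumen compartment with optional coupling
    constraints; and secretome profiling with hypergeometric flux
    enrichment. Deterministic toy host and microbe generators with planted
    ground truth support end-to-end testing of every workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
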