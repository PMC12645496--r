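Package: gctov
Title: Mechanistic Oncolytic Virus and PAC-1 Therapy Modelling with
    Model-Informed Machine Learning for Granulosa Cell Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates combination therapy of granulosa cell tumors of the
    ovary with a TRAIL-producing oncolytic virus and the procaspase-3
    activator PAC-1, using a nonlinear ordinary differential equation model
    of the tumor cell cycle (quiescent, G1 and transit-compartment active
    phases), viral infection and lysis, innate cytokine-phagocyte responses,
    two-compartment PAC-1 pharmacokinetics and target-mediated TRAIL
    disposition, coupled through an Emax/Hill pharmacodynamic effect.
    Provides local parameter sensitivity analysis, synthetic virtual-patient
    cohort generation, per-patient mechanistic feature enrichment of clinical
    tables, and a machine-learning evaluation harness (cross-validated linear
    regression and repeated single-hidden-layer neural networks) comparing
    prediction with and without model-derived features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
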