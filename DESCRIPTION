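Package: exflux
Title: Extracellular Flux and Growth Parameter Estimation from Time-Course Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell growth parameters (growth rate, lag time) and
    extracellular uptake and production fluxes by fitting time-course
    concentrations of biomass and extracellular metabolites with pluggable
    growth models. Parameters are estimated by weighted least squares using
    differential evolution followed by bounded quasi-Newton refinement;
    uncertainty is quantified by a parametric-bootstrap Monte-Carlo analysis;
    goodness-of-fit is assessed with a chi-squared test and candidate models
    are ranked by AIC and AICc. Ships five built-in growth models
    (exponential growth with optional lag phase and first-order metabolite
    degradation, and a dynamic Monod model), a template for user-defined
    models, a synthetic-data generator for validation, tab-separated input
    and output, YAML run configurations and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
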