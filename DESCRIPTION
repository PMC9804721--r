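Package: thermoniche
Title: Temperature-Dependent Consumer-Resource Models and Realized Thermal Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bioenergetic consumer-resource models with temperature-dependent
    vital rates, for studying how resource limitation reshapes a consumer's
    thermal performance curve (TPC). Couples a unimodal ingestion rate and
    exponentially increasing respiration with either a chemostat resource
    supply or a sign-constrained temperature-dependent logistic resource.
    Provides closed-form equilibria with analytic Jacobians, equilibrium
    branch scans with transcritical and Hopf bifurcation detection, numerical
    integration and limit-cycle summaries, zero-net-growth-isocline (R*)
    geometry of the realized thermal niche, thermal-mismatch regime diagrams,
    and a metabolic-meltdown diagnostic. Results are tidy tibbles with broom
    tidiers and ggplot2 autoplot methods; a thin command-line interface is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
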