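Package: protoflux
Title: Protocell Protometabolism Simulation with Nucleotide Catalytic Feedbacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth and division of autotrophic protocells driven by
    CO2 fixation at iron-sulfur clusters. A branching protometabolic network allocates
    fixed two-carbon units among fatty acids, two amino-acid pools, sugars and an
    energy currency; nucleotides synthesized from the latter three feed back as
    catalysts of CO2 fixation, of individual branches and of their own synthesis.
    Cells divide when the fatty-acid (membrane) count reaches a threshold, with
    deterministic or binomial (stochastic-segregation) partitioning of molecules.
    Provides event-detecting ODE integration of lineages, steady-state division-rate
    and equilibrium-concentration estimation, and a config-driven experiment layer for
    parameter sweeps and autocatalysis heat maps, returning tidy tibbles with ggplot2
    autoplot methods.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
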