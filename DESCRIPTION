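Package: rulescale
Title: Rule-Based Multi-Scale Qualitative Simulation of Drug Effect Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A qualitative, asynchronous rule-based simulation platform for
    multi-scale physiological models spanning molecules, cells and organs.
    Components carry discretely-valued attributes (low/normal/high,
    open/close, absent/present); condition->action rules fire one at a time
    in random order, and per-component rule-execution thresholds separate
    fast molecular responses from slow organ-level state changes.  Includes
    Monte Carlo ensemble simulation with drug-effect-pathway graph
    extraction (SIF/DOT export), combination-drug efficacy screening, rule
    converters from ODE systems (finite-difference monotonicity analysis)
    and from Petri nets, a reconstructed miniature type-2-diabetes model
    with a 22-drug catalogue, a parameterised random model generator, and
    an exhaustive brute-force oracle for validating the stochastic engine
    on tiny models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
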