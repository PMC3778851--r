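Package: tecgen
Title: Simulation Code Generation for CellML Models with Exchangeable ODE
    Solving Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage simulation compiler for cellular physiology models.
    Stage one symbolically weaves a CellML-style cell model (variables,
    initial values, MathML content-markup equations) together with an
    explicit ODE solving scheme described in TecML and a RelML variable-role
    map, producing a flat, ordered, single-assignment time-evolution
    equation set. Stage two emits runnable simulation source code (R or C)
    from that equation set. A reference interpreter executes flat programs
    directly in double precision or in configurable-precision decimal
    floating-point arithmetic, and a convergence-study driver measures
    root-mean-square error against a high-accuracy reference run and fits
    empirical convergence orders. Ships pinned Euler, Heun (modified Euler),
    midpoint and classical Runge-Kutta schemes, a FitzHugh-Nagumo fixture
    model, and a seeded random model generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    tibble,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
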