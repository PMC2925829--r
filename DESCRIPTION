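Package: kinsolve
Title: Kinetic Modeling of Biochemical Networks with Dynamic Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A workbench for kinetic modeling of biochemical reaction
    networks. Builds models from reaction-list text (stoichiometric matrix,
    mass-action rate templates, exact integer conservation laws, reduced
    ODE system), integrates them with a stiff-capable solver, scans
    explicitly defined functions, locates steady states by damped Newton
    iteration and traces them over a parameter by pseudo-arclength
    continuation with fold, Hopf and focus-node bifurcation detection,
    computes metabolic control coefficients, and fits parameters to
    time-course, steady-state and explicit-function data with four
    objective functions and linearized post-fit statistics. Simulation
    results can be bound to visual pathway maps and animated: node circle
    radii follow concentrations and arrow thicknesses or bar heights follow
    reaction rates through a clamped linear scaling, with export to SVG,
    PNG and AVI video. Models exchange with SBML Level 2 Version 4 on a
    declared subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
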