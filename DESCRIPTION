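Package: monolayermix
Title: Thermodynamic Analysis of Two-Component Langmuir Monolayer Isotherms
Version: 0.1.0
Authors@R: person("Film", "Balance Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the thermodynamic analysis of surface pressure-area
    (pi-A) compression isotherms of one- and two-component Langmuir
    monolayers at the air/water interface. Reads and writes a plain-text
    isotherm format, extracts clean compression branches, computes mean
    molecular areas at target surface pressures, ideal-mixing lines, excess
    molecular areas, excess Gibbs free energies of mixing by isotherm
    integration, and compressibility moduli with two-dimensional phase
    classification and phase-transition detection. Includes a seeded
    synthetic-isotherm generator (Volmer-type equation of state with
    optional liquid-expanded/liquid-condensed plateau and a regular-solution
    excess term) so that every analysis stage can be validated against
    closed-form ground truth, and a command-line style pipeline that
    orchestrates simulate, analyze and report stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
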