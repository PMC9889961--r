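Package: hybkit
Title: Interchange of Kinetic Models Between SBML and the HMOD Text Format
    with Neural-Network Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Round-trips kinetic systems-biology models between SBML
    (Level 3, with Level 2 read compatibility) and HMOD, a block-structured
    ASCII model format, and compiles trained feedforward artificial neural
    networks into standard SBML constructs (constant parameters plus
    assignment rules wired to reaction rates), producing hybrid
    semiparametric models that remain loadable by ordinary SBML tooling.
    Includes an expression layer translating content MathML to infix text
    and back, structural validators for both formats, a deterministic ODE
    simulator used to verify round-trip and compilation equivalence, a
    seeded fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
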