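Package: cellrad
Title: Cellular Dosimetry and Clonogenic Radiobiology for Alpha- and
    Beta-Emitting Radioligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vitro dosimetry and radiobiology of targeted
    radionuclide therapy experiments. Computes closed-form cumulated
    activities for branched decay chains (the Bi-213 chain and single
    nuclides such as Lu-177), mean absorbed dose to the bottom cell layer
    of a 6-well plate from radioactive incubation medium using tabulated
    layer S-values, MIRD-schema cellular self- and surface-dose from
    specifically bound activity, receptor-binding uptake kinetics, and
    linear-quadratic or linear-exponential clonogenic survival-curve
    fitting with dose at fixed survival and relative biological
    effectiveness (RBE). Includes seeded synthetic-data generators
    emulating clonogenic and uptake assays so the full pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
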