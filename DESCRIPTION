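Package: thermotogaH2
Title: Kinetic Modelling of Batch Biohydrogen Production by Thermotoga maritima
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates batch dark-fermentation of glucose, yeast extract and
    thiosulfate by the hyperthermophile Thermotoga maritima with a coupled ODE
    model: multi-substrate Monod growth with dissolved-hydrogen product
    inhibition, inhibition-dependent acetate/lactate/H2/CO2 stoichiometry,
    thiosulfate reduction to H2S, CO2/HCO3- and H2S/HS- speciation, and
    gas-liquid mass transfer with nitrogen stripping of the headspace.
    Includes the companion parameter-estimation procedures (yield regressions
    with equivalence extrapolation, apparent half-saturation constants, Pirt
    maintenance correction, critical dissolved-H2 extrapolation, inhibition
    exponent selection), dynamic gassing-out kLa estimation with diffusivity
    scaling, a synthetic-data generator with known ground truth for every
    estimation stage, validity-domain classification, and delimited-text /
    YAML / JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
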