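Package: emwsoil
Title: Soil Structure and Carbon Accounting for Rock-Amended Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for soil physicochemical responses to enhanced
    mineral weathering (crushed basalt or lime amendment) in tilled cropland.
    Fits the bimodal Kosugi soil water retention and hydraulic conductivity
    model to laboratory retention data, derives standard water points (field
    capacity, permanent wilting point, plant-available water, porosity),
    transforms fitted retention curves and particle-size distributions into
    pore-size distributions via the Young-Laplace relationship, and scores
    soil structural development with a Kullback-Leibler divergence index
    against a texture-derived reference soil. Also provides aggregate
    size-class bookkeeping (sand correction, organic-carbon enrichment
    factors and contributions), rock-amendment dilution mass balance,
    FAO/USDA texture-triangle classification, the routine group statistics
    the trial design calls for, and a synthetic-data generator emulating the
    field design so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
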