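Package: phageion
Title: Ion Thresholds for Bacteriophage Infectivity and Microbiome Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying geochemical constraints on lytic
    bacteriophage infection. Fits four-parameter logistic dose-response
    curves to microplate growth or ammonium data in paired phage/no-phage
    conditions to estimate ion IC50 and EC50 thresholds with bootstrap
    confidence intervals, converts thresholds to ionic strength, compares
    them with ion concentrations of natural environments, and models two
    mechanisms that transiently concentrate ions above infection thresholds:
    dilution of cytoplasmic ions released from lysed cells and evaporative
    concentration of dilute freshwaters with solubility ceilings. Includes
    synthetic-data generators with known ground truth for plate assays,
    nitrate-reducing community experiments, and environmental ion profiles,
    plus estimators of phage-cocktail effects on community nitrate reduction
    to ammonium (DNRA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
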