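Package: oleofuel
Title: Single-Cell-Oil Screening, Fermentation Kinetics and Biodiesel
    Property Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for microbial single-cell-oil workflows on
    lignocellulosic hydrolysates: Nile-red fluorescence screening analytics,
    batch fermentation kinetics and mass accounting (dry cell weight, lipid
    titre, sugar consumption), hydrolysate composition bookkeeping before and
    after cultivation, and estimation of biodiesel fuel properties (cetane
    number, iodine value, kinematic viscosity, density, cold filter plugging
    point, heating value) from fatty-acid methyl-ester weight-percent
    profiles via empirical composition-based correlations, with compliance
    checks against EN 14214, ASTM D6751 and IS 15607 limits. Includes seeded
    synthetic-data generators (logistic growth with Luedeking-Piret lipid
    kinetics, Dirichlet compositional profiles, correlation-calibrated
    screening tables) so the full pipeline is testable without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
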