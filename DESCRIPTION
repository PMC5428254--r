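Package: isocow
Title: Mechanistic Oxygen-Isotope Mass Balance of Cattle Body Water and Hair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily mechanistic simulator of oxygen flow through the body
    water of cattle. Every oxygen input flux (air O uptake, inhaled vapor,
    chemically bound feed O, feed moisture, drinking water) and output flux
    (CO2, respiratory and transcutaneous vapor, milk, organic products, urea,
    and the unfractionated fecal/urinary/sweat remainder) is computed in
    moles of O atoms per day from weather, husbandry and feed drivers, closed
    against water and oxygen mass balances, and propagated through a
    body-water turnover recursion to predict daily delta-18O of body water,
    of all output fluxes, and of tail hair keratin. Includes a synthetic
    driver generator for temperate grazing systems, position-time dating of
    hair segments, recovery of growth-rate and keratin-fractionation
    parameters, relative-isoflux attribution, and hold-constant variance
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
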