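Package: snifferch4
Title: Enteric Methane Prediction from Breath CH4/CO2 Ratios in Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting enteric methane (CH4) emissions of
    lactating dairy cows from the CH4/CO2 concentration ratio in breath sampled
    at an automatic milking system (the "sniffer" method). Processes 1-Hz gas
    traces into background-corrected per-visit ratios and eructation rates,
    computes ventilated head-box calorimetry fluxes, applies and refits linear
    prediction equations for daily CH4 (L/day) and the methane conversion
    factor (J/100 J gross energy intake), implements the CO2-tracer prediction
    from heat producing units (HPU), adjusts ratios for the time elapsed since
    the last eating bout with a linear mixed model, and evaluates predictions
    against observed emissions with through-origin regressions. Includes a
    synthetic-data generator emulating the statistical structure of the
    measurement campaign so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
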