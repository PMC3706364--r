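Package: cvdmicrosim
Title: Microsimulation of Tobacco Control and Cardiovascular Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-time microsimulation of myocardial infarction and
    stroke mortality in a population stratified by age, gender and
    urban/rural location, with correlated individual risk-factor profiles
    sampled through a Gaussian copula. Simulates tobacco-control policies
    (smoke-free laws, brief cessation advice, mass media campaigns,
    advertising bans, and excise-tax increases acting through price
    elasticities), pharmacological therapy expansion (aspirin,
    antihypertensives, statins), and their combinations, with exponential
    decay of excess cardiovascular risk after cessation. Paired
    common-random-number runs yield deaths-averted estimates and Monte
    Carlo 95% uncertainty intervals; a synthetic parameter generator
    provides India-like inputs for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
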