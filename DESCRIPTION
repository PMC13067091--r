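Package: botanrisk
Title: Probabilistic Risk-Benefit Assessment of Elements in Botanical Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo risk-benefit assessment of essential (Ca, K, P, Mg,
    Fe, Zn) and potentially toxic (Al, As, Ni, Pb) element intake from
    chronic consumption of botanical extracts in the adult diet. Provides a
    unit-aware registry of dietary reference values, health-based guidance
    values and reference points; parametric distribution fitting with AIC
    model selection; seeded lognormal/exponential exposure simulation under
    baseline-diet, botanicals-only, combined and acute scenarios; benefit
    (percent of dietary reference value) and risk (percent of tolerable
    intake, margin of exposure) metrics; cumulative non-carcinogenic risk
    via target hazard quotients and the hazard index under dose addition;
    and Spearman rank-correlation sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
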