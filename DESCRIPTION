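Package: dietrisk
Title: Probabilistic Dietary Heavy-Metal Health-Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates human health risks from heavy-metal intake via a staple
    food using the standard USEPA exposure framework: estimated daily intake
    (EDI), hazard quotient (HQ) and hazard index (HI) for non-carcinogenic
    risk, and slope-factor based carcinogenic risk (CR) with its total (TCR).
    Uncertainty is propagated by Monte Carlo simulation over lognormal
    concentration models (fitted by moment matching to geometric-mean and
    arithmetic-SD summaries) and intake-rate/body-weight models, with
    percentile reporting from P50 to P99.9. Includes a synthetic-data
    generator that emulates a stratified market-basket survey of rice
    contamination (Cd, As, Pb, Cu across seven provinces of Nepal),
    regulatory screening against FAO/WHO maximum allowable concentrations,
    and a config-driven pipeline with reproducible seeded runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
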