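Package: cbpricer
Title: Cost-Based Pricing of Drugs with Expanding Indications
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cost-based pricing (CBP) model for pharmaceuticals
    whose label expands over time to new indications. Per-treatment and
    per-vial prices are built up from amortized research and development
    costs, per-gram manufacturing costs, and profit and sales-and-marketing
    margins, with the eligible patient population projected from incidence
    rates, a regional population table, a multiplicative eligibility
    cascade and competitor-dependent market share over the remaining
    patent period. Supports cumulative yearly prices, cumulative prices
    per indication, and non-cumulative indication-based prices, plus a
    stepwise deterministic sensitivity analysis and a ten-scenario engine.
    Ships reconstructed case-study profiles for daratumumab and
    pembrolizumab and a seeded synthetic-profile generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
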