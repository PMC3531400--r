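Package: afhscost
Title: Ingredients-Based Costing of Scaling Up Adolescent-Friendly Health
    Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up, ingredients-based costing model for scaling up
    adolescent-friendly health services in 74 low- and middle-income
    countries over 2011-2015. Projects the population in need per country,
    intervention and year, builds linear coverage scale-up trajectories
    towards universal-access targets, costs the incremental service volume
    from ingredient quantities and delivery-level unit prices, adds
    programme-activity costs (management, training, supervision, IEC,
    infrastructure), and aggregates the resulting cost cube into price-tag
    reports by year, region, intervention group, cost category and income
    group. Includes a seeded synthetic-configuration generator standing in
    for unit-price and ingredient databases, and a hand-computable worked
    example used as an end-to-end regression fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
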