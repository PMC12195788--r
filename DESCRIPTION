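Package: basketcost
Title: Construction and Cost Analysis of Healthy and Sustainable Food Baskets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a healthy and sustainable basic food basket by allocating
    EAT-Lancet food-group gram targets across the items a reference population
    actually buys, adjusts purchase quantities with edible-portion / food
    transformation factors, aggregates energy and macronutrients, assembles a
    continuous monthly item-price panel from consumer-price-index segments
    (splicing across base years, admissible-range outlier screening,
    nearest-neighbour imputation), and compares the basket's minimum-price
    monthly cost against a reference basic food basket, including seasonal gap
    analysis, USD conversion and Orshansky poverty-line arithmetic. Ships a
    seeded synthetic-data generator for household-survey, price-panel,
    exchange-rate and reference-cost inputs so the full pipeline runs and is
    testable without restricted microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
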