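Package: heisnutr
Title: Nutrient Availability from Household Expenditure Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts food-purchase records from household expenditure and
    income surveys (HEIS) into daily per-equivalent-adult availability of six
    nutrients (energy, protein, vitamins A and C, iron, zinc). Implements the
    full conversion-table construction workflow: validation and coverage
    accounting of expenditure-category catalogs paired with multi-source food
    composition tables, standardization to 100 g of edible portion with
    retinol activity equivalents for vitamin A, Tukey-fence outlier screening
    with elimination of multi-outlier food items, and mean or median
    aggregation per category. Purchase microdata are converted with an
    adult-equivalence scale and a configurable reference period, and
    population-level estimates (overall, by year, and by income quintile)
    carry design-based 95% confidence intervals from stratified two-stage
    survey designs via Taylor linearization. A seeded generator of
    ENIGH-like synthetic surveys makes every stage testable without
    microdata access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
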