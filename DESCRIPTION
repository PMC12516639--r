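Package: adaudit
Title: Outdoor Food Advertising Audits with Nutrient Profiling and
    Deprivation Exposure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing outdoor food advertising and its relationship
    with area deprivation. Provides a four-level audit data model (images,
    assets, adverts, products) with CSV/GeoJSON serialisation; a seeded
    synthetic-audit generator for desk-scale method testing; stratified
    neighbourhood sampling by deprivation quintile with block-randomised
    visit order; product scoring under the UK Food Standards Agency 2004/05
    Nutrient Profile Model (HFSS classification); advert classification
    against a hypothetical Healthier Food Advertising Policy; geodesic
    boundary filtering with buffer sensitivity analysis; and reliability
    (Cohen's kappa) and exposure (chi-square with Cochran validity)
    statistics with Table-style summary outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
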