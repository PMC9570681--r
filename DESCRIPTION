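Package: cfni
Title: Charitable Food Nutrition Index from Stoplight Tier-Ranked Food Assortments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the nutritional quality of food assortments
    ("client carts") in the charitable food system. Ranks individual food
    items into green/yellow/red stoplight tiers from category-specific
    per-serving thresholds on saturated fat, sodium and added sugar; scores
    carts with a configuration-driven Healthy Eating Index 2015 (HEI-2015)
    engine; learns tier weights that maximise correlation with HEI by ridge
    or ordinary least squares regression; rescales the fitted model into a
    0-100 Charitable Food Nutrition Index (CFNI); and evaluates the index by
    k-fold cross-validated correlation. Includes a calibrated synthetic cart
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
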