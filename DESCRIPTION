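Package: carbheat
Title: Heats of Combustion of the Carbohydrate Mass in Vegetal Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the heat of combustion of the carbohydrate mass
    contained in fruits, vegetables and cereals. Provides per-carbohydrate
    reference values and overall intervals (with macronutrient-contamination
    correction, hydrated/anhydrous conversion and outlier screening),
    food-level global intervals obtained by exhaustive enumeration of
    composition-interval and heat-interval endpoints, group-level
    generalized expressions built from a length-measure quantile rule, and
    a synthetic composition-table generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
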