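Package: tweetscape
Title: Neighborhood Well-Being and Health-Behavior Indicators from Geotagged Social Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns streams of geolocated short-text posts into area-level
    (census-tract-like and zip-code-like) indicators of happiness, food
    culture, and physical activity. Provides post cleaning and tokenization,
    a bounding-box-tree point-in-polygon spatial join, a maximum-entropy
    (penalized logistic) sentiment classifier with cutpoint calibration,
    lexicon-based food and physical-activity mention detection with caloric
    density and MET-based exercise-intensity scoring, per-area aggregation,
    and association statistics: z-standardization, an economic-disadvantage
    factor score, OLS with county-clustered robust standard errors, and
    Moran's I spatial autocorrelation. A synthetic-data generator with known
    ground truth makes the whole pipeline testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
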