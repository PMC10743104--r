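Package: dietdiv
Title: Dietary Diversity Scoring and Tertile Association Analysis for
    24-Hour Recall Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the dietary diversity score (DDS; quartile-based
    points over five food groups relative to age-group-wide food totals)
    and the food variety score (FVS; distinct over total foods) from
    multi-day 24-hour dietary recall data, derives diet-quality and
    health-status metrics (energy and percent-of-energy macronutrients,
    fiber, dietary energy density, ultra-processed-food energy share and
    quintiles, FFQ propensity ratios, HOMA-IR, BMI categories), and runs
    tertile-based association analyses: covariate-adjusted marginal means
    with Bonferroni-corrected pairwise contrasts and logistic regression
    of overweight/obesity on score tertiles. Includes a synthetic
    multi-country cohort generator with injectable diversity effects so
    the full pipeline is testable without access-restricted study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
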