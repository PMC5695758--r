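Package: hazshift
Title: Whole-Population Shifts in Child Height-for-Age Z-Score Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the distribution of height-for-age Z-scores
    (HAZ) in children aged 0-36 months changes as the population mean declines
    with age. Provides a hierarchical synthetic-data generator emulating
    multi-country household surveys with probability weights; survey-weighted
    distributional parameters (mean, median, SD, 5th and 95th percentiles) over
    91.3-day age bands; pooled age-band summaries with cluster-robust confidence
    intervals; three-level linear mixed models with random survey slopes, ICCs
    and BLUP survey slopes relating distributional parameters to sign-reversed
    mean HAZ; and a Monte Carlo simulator contrasting subgroup versus
    whole-population growth faltering, validated against a closed-form
    mixture-moments oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
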