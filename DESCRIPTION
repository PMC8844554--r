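Package: trialcea
Title: Trial-Based Lifetime Cost-Utility Analysis with a Diabetes
    Complications Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-level cost-utility analysis of two-arm
    trials in type 2 diabetes, from trial data to lifetime
    cost-effectiveness. Generates synthetic trial-like cohorts with known
    ground truth; imputes missing EQ-5D utilities and cardiovascular risk
    factors by chained equations with predictive mean matching; values
    EQ-5D profiles with configurable value sets and a 5L-to-3L crosswalk;
    computes within-trial QALYs (area under the curve, baseline adjusted)
    and costs with annual discounting; extrapolates to a lifetime horizon
    with an annual-cycle microsimulation of eight diabetes complications
    and death driven by configurable parametric risk equations; and
    propagates uncertainty by patient bootstrap crossed with multiple
    imputation plus risk-equation coefficient draws, producing ICERs,
    percentile confidence intervals, cost-effectiveness planes,
    acceptability curves, price-discount sensitivity analyses, treatment
    discontinuation scenarios, and subgroup results.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
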