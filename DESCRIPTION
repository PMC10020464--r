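Package: lamprisk
Title: Significant Pattern Mining and Risk Stratification for Heart
    Failure Onset
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines all statistically significant combinations (up to four
    factors) of binarized clinical variables that predict a binary outcome
    such as new-onset heart failure, using the limitless-arity
    multiple-testing procedure (LAMP) with a Tarone-calibrated Bonferroni
    factor over the testable hypotheses, then stratifies an independent
    validation cohort by the number of matched predictive combinations:
    per-stratum incidence, a Cochran-Armitage trend test and discrete-time
    Kaplan-Meier curves. Includes a seedable synthetic-cohort simulator
    that emulates annual health check-up data with planted risk
    combinations, so the whole two-cohort design can be exercised without
    access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
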