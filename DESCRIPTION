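Package: periglyc
Title: Peri-Exercise Glycemia from CGM Traces and Exercise Logbooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments continuous glucose monitoring (CGM) time around
    free-living physical-activity sessions into five prioritized peri-exercise
    windows (pre-exercise, during, early recovery, late recovery, non-exercise),
    computes pooled glucose band metrics (time below/in/above range) per window
    class, classifies logbook-reported hypoglycemia episodes and behavioural
    adjustments (temporary glucose targets, carbohydrate intake) against
    exercise-management guidance, and fits mixed-effects logistic regressions of
    per-session hypoglycemia on guideline-deviation flags via adaptive
    Gauss-Hermite quadrature. Includes a seeded synthetic cohort generator whose
    defaults emulate a one-month free-living cohort of adults with type 1
    diabetes using automated insulin delivery systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
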