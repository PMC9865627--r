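Package: vo2step
Title: VO2max Estimation from a Submaximal Step Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates maximal oxygen consumption (VO2max) from a submaximal
    three-stage step test with two recovery stages. Implements the step-test
    heart-rate index, a fixed-coefficient multiple regression estimator, a
    per-subject linear extrapolation of heart rate against stage-constant
    oxygen-uptake values up to the age-predicted maximal heart rate, and a
    combined rule that switches from the regression estimator to the
    extrapolation estimator above a fitness cut-off. Includes the
    method-comparison statistics used to validate such estimators (constant
    error, standard error of the estimate, total error, Pearson correlation,
    and Bland-Altman fixed and proportional bias with 95% limits of
    agreement), a synthetic cohort generator for end-to-end exercising of the
    pipeline, and delimited-file input/output with command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
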