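Package: spirolms
Title: Spirometry Reference Equations by the LMS Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and evaluates normative spirometry reference equations
    with the lambda-mu-sigma (LMS) method under the Box-Cox Cole-Green
    distribution.  Provides the BCCG distribution functions (density, CDF,
    quantile, sampling, z-transform), maximum-likelihood fitting of median,
    coefficient-of-variation and skewness curves on log-age, log-height and
    age splines with AIC/SBC degrees-of-freedom selection, lower-limit-of-
    normal and Z-score computation, reference lookup tables, cohort-level
    comparison summaries (age-group Z-score tests against zero, below-LLN
    frequency tables, Bland-Altman agreement), and a seeded synthetic-cohort
    generator for end-to-end validation against a known true model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
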