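Package: greygrowth
Title: Grey GM(1,1) Modelling of Preschool Anthropometric Trends
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the grey first-order one-variable prediction model GM(1,1)
    to short, positive, equidistant time series, with the accumulating
    generation operator, adjacent-mean regression, closed-form least-squares
    parameter estimation, a restored exponential response function, and the
    posterior-variance accuracy battery (mean relative error, C ratio, small
    error probability, four-level grading).  Packages a full secular-trend
    analysis of Chinese preschool anthropometry (height, weight, chest
    circumference, BMI by sex and age over the 2000-2020 national surveys)
    with 2025/2030 forecasts and overweight/obesity prevalence projections,
    plus a synthetic-series generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
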