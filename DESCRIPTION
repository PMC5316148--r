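Package: pedscreen
Title: Simplified Overweight Screening for School-Age Children from LMS
    Growth References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening school-age children (5-19 years) for
    overweight from weight and height alone. Implements the LMS (Box-Cox
    power, median, coefficient of variation) growth-reference machinery:
    z-scores, their inverse, and percentile values with age interpolation;
    the direct BMI-for-age classification against the +1 SD cutoff; the
    construction and application of simplified sex-specific screening
    tables that give, for each half-year age row and reference height
    percentile, the weight at which a child crosses the +1 SD BMI-for-age
    cutoff; duplicate-measurement reconciliation rules for field
    anthropometry; overall, positive and negative percent agreement on the
    2x2 cross-classification of the two methods; and a synthetic cohort
    generator emulating a clinic population of 6-11 year olds so the full
    validation pipeline can be exercised without patient data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
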