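Package: normbrain
Title: Age-Based Normative Modelling of Longitudinal Brain Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normative ("null") models of healthy brain aging from
    longitudinal MRI-derived regional biomarkers and uses them for residual-based
    classification and early prediction of conversion to mild cognitive
    impairment (MCI) and Alzheimer's disease (AD). Healthy-control subjects with
    a normal cerebrospinal-fluid (CSF) amyloid/tau profile define the null
    cohort; each region of interest is modelled with a random-intercept linear
    mixed-effects model with age and education as fixed effects, regions are
    classified as variant or quasi-variant by their annual standardized change,
    and subject-specific baseline intercepts of variant regions are inferred
    from quasi-variant regions via kernel partial least squares regression.
    Deviations of observed values from the age-expected trajectory feed
    subject-grouped support-vector-machine classifiers for HC/MCI/AD
    discrimination and for quantifying how many years the model anticipates the
    clinical diagnosis. Includes a synthetic longitudinal cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    e1071,
    MASS,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
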