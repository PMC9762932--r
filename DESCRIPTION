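Package: alsyield
Title: Clinical Actionability of ALS Genetic Testing and Age-Restriction
    Policy Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether an amyotrophic lateral sclerosis (ALS)
    genetic test result is clinically actionable, and to estimate how many
    actionable results an age-restricted testing policy misses. Implements
    rare-variant site and sample quality control, consequence-impact
    prioritisation, an ACMG/AMP 28-criterion classification engine with
    fixed-value approximation of the manually reviewed criteria and
    sub-stratification of variants of uncertain significance,
    repeat-expansion interpretation for C9orf72 and ATXN2, gene-panel and
    inheritance-mode actionability logic with a database corroboration rule,
    age-stratified diagnostic-yield estimation with binomial confidence
    intervals, directly standardized incidence with gamma (Fay-Feuer style)
    exact intervals, and a missed-diagnosis estimator for age-restricted
    testing policies. A synthetic-cohort and incidence-register generator
    with planted ground truth makes every stage testable without
    access-controlled data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
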