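# published UK surveillance inputs used by the policy model

#' UK ALS incidence and expected sporadic diagnoses, 2018-2019
#'
#' Age- and sex-specific ALS incidence rates per 100,000 person-years from
#' the national motor neuron disease register of England, Wales and Northern
#' Ireland (diagnoses 2018-2019), together with the expected number of new
#' *sporadic* ALS diagnoses per year in the UK, directly standardized to the
#' 2011 census population and adjusted by the 0.875 sporadic factor. These
#' are published point estimates with 95% intervals, transcribed as an input
#' table for the policy estimator.
#'
#' @return Tibble with columns `age_group`, `sex`, `rate`, `rate_lower`,
#'   `rate_upper`, `expected`, `expected_lower`, `expected_upper`.
#' @export
uk_als_incidence <- function() {
  tibble::tribble(
    ~age_group, ~sex, ~rate, ~rate_lower, ~rate_upper,
    ~expected, ~expected_lower, ~expected_upper,
    "<40", "male", 0.080, 0.022, 0.20, 7.03, 1.92, 18.01,
    "<40", "female", 0.020, 0.0005, 0.011, 1.78, 0.045, 9.91,
    "40-49", "male", 0.89, 0.54, 1.38, 35.74, 21.83, 55.19,
    "40-49", "female", 0.40, 0.18, 0.75, 16.24, 7.43, 30.83,
    "50-59", "male", 2.67, 1.98, 3.53, 89.11, 65.92, 117.81,
    "50-59", "female", 0.80, 0.45, 1.32, 27.35, 15.31, 45.12,
    "60-69", "male", 3.19, 2.38, 4.20, 93.03, 69.27, 122.32,
    "60-69", "female", 2.91, 2.15, 3.85, 89.05, 65.88, 117.73,
    ">=70", "male", 3.65, 2.75, 4.73, 99.90, 75.46, 129.73,
    ">=70", "female", 3.20, 2.48, 4.08, 118.52, 91.66, 150.79
  )
}

#' Back-calculated standard populations per age-sex cell
#'
#' The per-cell standard population sizes behind [uk_als_incidence()] are not
#' published directly; they are recovered here from the published expected
#' counts, rates and sporadic factor as
#' `standard_pop = expected * 1e5 / (rate * 0.875)`. A derived
#' reconstruction, adequate for building synthetic registers with realistic
#' structure.
#'
#' @return Tibble with columns `age_group`, `sex`, `standard_pop`.
#' @export
uk_standard_population <- function() {
  uk_als_incidence() %>%
    transmute(
      .data$age_group, .data$sex,
      standard_pop = .data$expected * 1e5 / (.data$rate * 0.875)
    )
}

#' Age-group probabilities of a clinically actionable result (UK)
#'
#' Published point estimates for the UK cohort: with the Genomics England
#' panel, 0.23 in the youngest (<40) and 0.17 in the oldest (>=70) onset
#' group; with the four-gene panel, 0.11 and 0.06. The probabilities for the
#' three middle groups are not published at this granularity; they are set to
#' a single flat value per panel (0.222 and 0.122) calibrated so that the
#' policy model's expected annual actionable counts match the published
#' annual totals given [uk_als_incidence()]. See the methods vignette for the
#' derivation.
#'
#' @param panel `"genomics_england"` (default) or `"four_gene"`.
#' @return Tibble with columns `age_group`, `p`.
#' @export
uk_actionable_probabilities <- function(panel = c(
                                          "genomics_england", "four_gene"
                                        )) {
  panel <- match.arg(panel)
  p <- switch(panel,
    genomics_england = c(0.23, 0.222, 0.222, 0.222, 0.17),
    four_gene = c(0.11, 0.122, 0.122, 0.122, 0.06)
  )
  tibble(age_group = age_group_levels(), p = p)
}
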