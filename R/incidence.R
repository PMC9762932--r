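# crude and directly standardized incidence, gamma exact intervals,
# sporadic-fraction adjustment, and the missed-actionable-results estimator

#' Policy configuration for the missed-results estimator
#'
#' @param sporadic_factor Multiplier converting all-ALS incidence to sporadic
#'   ALS incidence (default 0.875, the midpoint of the 80-95% sporadic
#'   share implied by a 5-20% familial fraction).
#' @param age_cutoff Age-restriction threshold in years; testing is assumed
#'   available only below this onset age. Must coincide with an age-group
#'   boundary (0, 40, 50, 60 or 70).
#' @param ci_level Confidence level for intervals (default 0.95).
#' @return A list of class `als_policy_config`.
#' @export
policy_config <- function(sporadic_factor = 0.875, age_cutoff = 40,
                          ci_level = 0.95) {
  check_prob(sporadic_factor, "sporadic_factor")
  if (!age_cutoff %in% age_group_lower()) {
    stop_config("`age_cutoff` must coincide with an age-group boundary (0, 40, 50, 60, 70).")
  }
  structure(
    list(
      sporadic_factor = sporadic_factor, age_cutoff = age_cutoff,
      ci_level = ci_level
    ),
    class = "als_policy_config"
  )
}

#' Crude incidence rate per 100,000 person-years
#'
#' @param cases Case count (vectorised).
#' @param person_years Person-years at risk (must be positive).
#' @return Numeric rate per 100,000 person-years.
#' @export
crude_rate <- function(cases, person_years) {
  if (any(person_years <= 0)) stop_input("`person_years` must be positive.")
  1e5 * cases / person_years
}

#' Expected diagnoses per year in a standard population
#'
#' Direct standardization at the stratum level: the crude rate applied to the
#' standard population of the same age-sex cell.
#'
#' @param rate Rate per 100,000 person-years.
#' @param standard_pop Standard population size for the cell.
#' @return Expected number of diagnoses per year.
#' @export
expected_count <- function(rate, standard_pop) {
  if (any(rate < 0 | standard_pop < 0)) {
    stop_input("`rate` and `standard_pop` must be non-negative.")
  }
  rate * standard_pop / 1e5
}

#' Gamma exact confidence interval for a weighted sum of Poisson counts
#'
#' For a directly standardized rate (or expected count) written as
#' `X = sum(w_i * d_i)` over strata with case counts `d_i` and per-case
#' weights `w_i`, the exact gamma approximation gives
#' `lower = qgamma(alpha/2, shape = X^2/V, scale = V/X)` with
#' `V = sum(w_i^2 * d_i)`, and
#' `upper = qgamma(1 - alpha/2, shape = (X+wM)^2/(V+wM^2),
#' scale = (V+wM^2)/(X+wM))` where `wM = max(w_i)`. When all counts are zero
#' the lower bound is 0. With a single stratum of weight 1 this reduces to
#' the Poisson exact (Garwood) interval.
#'
#' @param cases Integer vector of per-stratum case counts.
#' @param weights Per-case weight of each stratum (e.g.
#'   `standard_share * 1e5 / person_years` for a standardized rate per
#'   100,000).
#' @param level Confidence level.
#' @return Tibble with one row: `point`, `lower`, `upper`.
#' @export
gamma_ci <- function(cases, weights = rep(1, length(cases)), level = 0.95) {
  if (length(cases) == 0) stop_input("Need at least one stratum.")
  if (length(weights) != length(cases)) {
    stop_input("`cases` and `weights` must have the same length.")
  }
  if (any(cases < 0) || any(weights < 0)) {
    stop_input("`cases` and `weights` must be non-negative.")
  }
  alpha <- 1 - level
  x <- sum(weights * cases)
  v <- sum(weights^2 * cases)
  wm <- max(weights)
  lower <- if (x == 0) 0 else qgamma(alpha / 2, shape = x^2 / v, scale = v / x)
  upper <- qgamma(1 - alpha / 2,
    shape = (x + wm)^2 / (v + wm^2), scale = (v + wm^2) / (x + wm)
  )
  tibble(point = x, lower = lower, upper = upper)
}

#' Apply the sporadic-fraction adjustment
#'
#' Linear scaling of an all-ALS quantity (rate, expected count, or interval
#' bound) to its sporadic-only share.
#'
#' @param x Non-negative numeric vector.
#' @param config An [policy_config()] object.
#' @return `x * sporadic_factor`.
#' @export
sporadic_adjust <- function(x, config = policy_config()) {
  if (any(x < 0)) stop_input("`x` must be non-negative.")
  x * config$sporadic_factor
}

#' Incidence and expected-diagnosis table from a register
#'
#' Builds a surveillance-style table from age-sex register strata: crude
#' rates per 100,000 person-years with per-stratum gamma exact intervals, and
#' the expected number of new sporadic diagnoses per year obtained by direct
#' standardization to `standard_pop` and the sporadic-fraction adjustment
#' (intervals reuse the gamma method with weights scaled by
#' `sporadic_factor * standard_pop / person_years`).
#'
#' @param register Data frame with columns `age_group`, `sex`, `cases`,
#'   `person_years`, `standard_pop`.
#' @param config A [policy_config()] (supplies the sporadic factor and CI
#'   level).
#' @return Tibble with rate and expected-count estimates and intervals per
#'   stratum.
#' @export
incidence_table <- function(register, config = policy_config()) {
  check_columns(
    register, c("age_group", "sex", "cases", "person_years", "standard_pop"),
    "register"
  )
  register %>%
    as_tibble() %>%
    rowwise() %>%
    mutate(
      rate = crude_rate(.data$cases, .data$person_years),
      rate_ci = list(gamma_ci(.data$cases, 1e5 / .data$person_years,
        level = config$ci_level
      )),
      expected = sporadic_adjust(
        expected_count(.data$rate, .data$standard_pop), config
      ),
      expected_ci = list(gamma_ci(
        .data$cases,
        config$sporadic_factor * .data$standard_pop / .data$person_years,
        level = config$ci_level
      ))
    ) %>%
    ungroup() %>%
    mutate(
      rate_lower = map_dbl(.data$rate_ci, "lower"),
      rate_upper = map_dbl(.data$rate_ci, "upper"),
      expected_lower = map_dbl(.data$expected_ci, "lower"),
      expected_upper = map_dbl(.data$expected_ci, "upper")
    ) %>%
    select(-"rate_ci", -"expected_ci")
}

#' Directly standardized rate across strata
#'
#' Weights stratum rates by a standard population's structure:
#' `sum(share_i * rate_i)` with `share_i = standard_pop_i / sum(standard_pop)`,
#' with a gamma exact interval. Using the study population itself as the
#' standard reproduces the crude overall rate exactly.
#'
#' @inheritParams incidence_table
#' @param level Confidence level.
#' @return Tibble with `point`, `lower`, `upper` (rate per 100,000
#'   person-years).
#' @export
standardized_rate <- function(register, level = 0.95) {
  check_columns(
    register, c("cases", "person_years", "standard_pop"), "register"
  )
  share <- register$standard_pop / sum(register$standard_pop)
  gamma_ci(register$cases, share * 1e5 / register$person_years, level = level)
}

#' Expected actionable results missed by an age-restricted testing policy
#'
#' Multiplies the age- (and optionally sex-) specific expected numbers of new
#' sporadic diagnoses per year by the age-group probabilities of a clinically
#' actionable genetic test result, sums the products over the age groups at
#' or above the testing cutoff (`missed`) and over all groups (`total`), and
#' reports the missed proportion with a Wald interval on the rounded counts
#' (`k = round(missed)`, `n = round(total)` — the scale on which such annual
#' counts are reported).
#'
#' @param expected Data frame with columns `age_group`, `expected` and
#'   optionally `sex` (e.g. from [incidence_table()], or a published table of
#'   expected annual diagnoses).
#' @param probabilities Data frame with columns `age_group`, `p` and
#'   optionally `sex`. Age-only probabilities (the default mode) are shared
#'   across sexes.
#' @param config A [policy_config()].
#' @return Object of class `als_missed`: a list with `missed`, `total`,
#'   `proportion`, `ci` (lower/upper), `by_sex`, `strata` and `config`.
#' @export
missed_estimate <- function(expected, probabilities,
                            config = policy_config()) {
  check_columns(expected, c("age_group", "expected"), "expected counts")
  check_columns(probabilities, c("age_group", "p"), "probabilities")
  check_prob(probabilities$p, "p")
  missing_groups <- setdiff(
    unique(as.character(expected$age_group)),
    unique(as.character(probabilities$age_group))
  )
  if (length(missing_groups) > 0) {
    stop_input(paste0(
      "No actionable probability supplied for age group(s): ",
      paste(missing_groups, collapse = ", ")
    ))
  }
  join_by <- "age_group"
  if ("sex" %in% names(probabilities) && "sex" %in% names(expected)) {
    join_by <- c("age_group", "sex")
  }
  expected <- expected %>% mutate(age_group = as.character(.data$age_group))
  probabilities <- probabilities %>%
    mutate(age_group = as.character(.data$age_group))
  strata <- expected %>%
    inner_join(probabilities, by = join_by) %>%
    mutate(
      contribution = .data$expected * .data$p,
      missed_stratum = age_group_lower()[.data$age_group] >= config$age_cutoff
    )
  missed <- sum(strata$contribution[strata$missed_stratum])
  total <- sum(strata$contribution)
  k <- round(missed)
  n <- round(total)
  ci <- if (n >= 1) {
    proportion_ci(k, n, level = config$ci_level)
  } else {
    tibble(p = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  by_sex <- if ("sex" %in% names(strata)) {
    strata %>%
      group_by(.data$sex) %>%
      summarise(
        missed = sum(.data$contribution[.data$missed_stratum]),
        total = sum(.data$contribution), .groups = "drop"
      )
  } else {
    NULL
  }
  structure(
    list(
      missed = missed, total = total,
      proportion = if (total > 0) missed / total else NA_real_,
      ci = c(lower = ci$lower, upper = ci$upper),
      by_sex = by_sex, strata = as_tibble(strata), config = config
    ),
    class = "als_missed"
  )
}

#' @method print als_missed
#' @export
print.als_missed <- function(x, ...) {
  cat(
    "Age-restricted testing policy (cutoff ", x$config$age_cutoff,
    " years):\n", sep = ""
  )
  cat(sprintf(
    "  missed %.1f of %.1f expected actionable results per year (%.0f%%, %d%%CI %.0f%%-%.0f%%)\n",
    x$missed, x$total, 100 * x$proportion,
    round(100 * x$config$ci_level),
    100 * x$ci[["lower"]], 100 * x$ci[["upper"]]
  ))
  invisible(x)
}

#' @method tidy als_missed
#' @export
tidy.als_missed <- function(x, ...) {
  x$strata %>%
    select(dplyr::any_of(c("age_group", "sex")), "expected", "p",
      "contribution",
      missed = "missed_stratum"
    )
}

#' @method glance als_missed
#' @export
glance.als_missed <- function(x, ...) {
  tibble(
    missed = x$missed, total = x$total, proportion = x$proportion,
    conf.low = x$ci[["lower"]], conf.high = x$ci[["upper"]],
    age_cutoff = x$config$age_cutoff,
    sporadic_factor = x$config$sporadic_factor
  )
}

#' Plot the missed-results breakdown of a policy estimate
#'
#' Expected actionable results per year by age group, split into tested and
#' missed under the age cutoff.
#'
#' @param object An `als_missed` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot als_missed
#' @export
autoplot.als_missed <- function(object, ...) {
  df <- object$strata %>%
    mutate(
      status = ifelse(.data$missed_stratum, "missed", "tested"),
      age_group = factor(.data$age_group, age_group_levels())
    )
  ggplot(df, aes(
    x = .data$age_group, y = .data$contribution, fill = .data$status
  )) +
    geom_col() +
    labs(
      x = "Age of onset (years)",
      y = "Expected actionable results per year",
      fill = NULL
    ) +
    theme_minimal()
}

#' Plot an incidence table
#'
#' Crude rates per 100,000 person-years with gamma exact intervals, by age
#' group and sex.
#'
#' @param x Output of [incidence_table()].
#' @return A ggplot object.
#' @export
plot_incidence <- function(x) {
  x <- x %>% mutate(age_group = factor(.data$age_group, age_group_levels()))
  pos <- position_dodge(width = 0.3)
  ggplot(x, aes(
    x = .data$age_group, y = .data$rate, colour = .data$sex,
    group = .data$sex
  )) +
    geom_point(position = pos) +
    geom_errorbar(aes(ymin = .data$rate_lower, ymax = .data$rate_upper),
      width = 0.2, position = pos
    ) +
    labs(
      x = "Age of onset (years)",
      y = "Incidence per 100,000 person-years", colour = NULL
    ) +
    theme_minimal()
}
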