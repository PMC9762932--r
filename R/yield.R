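# age-stratified diagnostic-yield proportions with binomial intervals

#' Binomial proportion with a confidence interval
#'
#' Computes `p = k/n` with either the Wald (normal-approximation) interval
#' `p +/- z * sqrt(p(1-p)/n)` — deliberately not clipped to `[0, 1]`, so an
#' upper bound above 1 is reported as such — or the exact Clopper-Pearson
#' interval. Values are returned at full precision; rounding is presentation
#' only.
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials (vectorised, `>= 1`).
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"exact"` (Clopper-Pearson).
#' @return Tibble with columns `p`, `lower`, `upper`.
#' @examples
#' proportion_ci(115, 117) # 0.98 (0.96-1.01) at 2 dp
#' @export
proportion_ci <- function(k, n, level = 0.95, method = c("wald", "exact")) {
  method <- match.arg(method)
  if (any(n < 1)) stop_input("`n` must be at least 1.")
  if (any(k < 0 | k > n)) stop_input("`k` must satisfy 0 <= k <= n.")
  p <- k / n
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lower <- p - half
    upper <- p + half
  } else {
    alpha <- 1 - level
    lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
    upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  }
  tibble(p = p, lower = lower, upper = upper)
}

#' Age-group (and sex) stratified actionable-yield table
#'
#' Tabulates, per panel and stratum, the number of persons tested (`n`), the
#' number with an actionable result (`k`), the proportion and its confidence
#' interval.
#'
#' @param actionability Result of [actionability()].
#' @param persons Data frame with `person_id`, `age_onset` (and `sex` when
#'   stratifying by sex); every person must have an age (persons with missing
#'   age must have been removed by sample QC upstream).
#' @param by Stratification columns: `"age_group"` (default) and/or `"sex"`.
#' @param level,method Passed to [proportion_ci()].
#' @return Tibble of class `als_yield` with columns `panel`, the strata,
#'   `n`, `k`, `p`, `lower`, `upper`.
#' @export
yield_table <- function(actionability, persons, by = "age_group",
                        level = 0.95, method = c("wald", "exact")) {
  method <- match.arg(method)
  check_columns(persons, c("person_id", "age_onset"), "persons")
  if (anyNA(persons$age_onset)) {
    abort(
      "Persons with missing age reached yield_table(); sample QC must remove them first.",
      class = "alsyield_internal_error"
    )
  }
  by <- match.arg(by, c("age_group", "sex"), several.ok = TRUE)
  persons <- persons %>% mutate(age_group = bin_age(.data$age_onset))
  joined <- actionability %>%
    inner_join(persons, by = "person_id")
  out <- joined %>%
    group_by(.data$panel, dplyr::pick(dplyr::all_of(by)), .drop = FALSE) %>%
    summarise(
      n = dplyr::n(), k = sum(.data$actionable), .groups = "drop"
    ) %>%
    filter(.data$n > 0 | .data$k > 0)
  ci <- proportion_ci(out$k, pmax(out$n, 1), level = level, method = method)
  out <- bind_cols(out, ci) %>% mutate(p = .data$k / pmax(.data$n, 1))
  class(out) <- c("als_yield", class(out))
  out
}

#' @method tidy als_yield
#' @export
tidy.als_yield <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Plot an actionable-yield table
#'
#' Yield by age group with error bars, one colour per panel (the usual way
#' such results are displayed).
#'
#' @param object An `als_yield` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot als_yield
#' @export
autoplot.als_yield <- function(object, ...) {
  pos <- position_dodge(width = 0.4)
  ggplot(object, aes(
    x = .data$age_group, y = .data$p,
    colour = .data$panel, group = .data$panel
  )) +
    geom_point(position = pos) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.2, position = pos
    ) +
    labs(
      x = "Age of onset (years)",
      y = "Probability of a clinically actionable result",
      colour = "Panel"
    ) +
    theme_minimal()
}
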