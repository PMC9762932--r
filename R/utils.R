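# shared small helpers: age grouping, rounding, error classes

#' Age-of-onset groups
#'
#' The five onset-age groups used throughout the package: `<40`, `40-49`,
#' `50-59`, `60-69`, `>=70`. Intervals are closed on the left, so an onset at
#' exactly 40 falls in `40-49` and at exactly 70 in `>=70`.
#'
#' @return Character vector of the five group labels, in age order.
#' @export
age_group_levels <- function() {
  c("<40", "40-49", "50-59", "60-69", ">=70")
}

# lower bound (years) of each age group, used by the policy cutoff
age_group_lower <- function() {
  c("<40" = 0, "40-49" = 40, "50-59" = 50, "60-69" = 60, ">=70" = 70)
}

#' Assign an age of onset to its age group
#'
#' @param age_onset Numeric vector of onset ages in years; `NA` propagates.
#' @return Factor with levels [age_group_levels()].
#' @examples
#' bin_age(c(39.9, 40, 55, 70))
#' @export
bin_age <- function(age_onset) {
  age_onset <- as.numeric(age_onset)
  if (any(age_onset < 0, na.rm = TRUE)) {
    abort("`age_onset` must be non-negative.", class = "alsyield_input_error")
  }
  cut(age_onset,
    breaks = c(0, 40, 50, 60, 70, Inf), right = FALSE,
    labels = age_group_levels(), include.lowest = TRUE
  )
}

# half-up rounding used for presentation only (stored values keep full precision)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_config <- function(msg) abort(msg, class = "alsyield_config_error")
stop_input <- function(msg) abort(msg, class = "alsyield_input_error")
stop_schema <- function(msg) abort(msg, class = "alsyield_schema_error")

check_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop_config(paste0("`", what, "` must lie in [0, 1]."))
  }
  invisible(x)
}

# required-column check with a schema error naming the missing field
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_schema(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
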