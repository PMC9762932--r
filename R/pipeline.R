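# end-to-end orchestration: QC -> prioritisation -> classification ->
# actionability -> yield -> (optional) incidence/policy estimates

#' Run the full actionability pipeline
#'
#' Executes the stages in order — sample QC, variant prioritisation, ACMG
#' classification, repeat interpretation, per-panel actionability,
#' age-stratified yield, and (when register material is supplied) the
#' incidence table and missed-results policy estimate — and returns a report
#' with stage-wise counts. Fully deterministic given its inputs; the seed is
#' recorded in the report header along with a hash of the configuration.
#'
#' @param cohort An `als_cohort` list (from [generate_cohort()]) or any list
#'   providing tibbles `persons`, `variants`, `repeat_calls`,
#'   `sample_metrics`.
#' @param panels Panel definitions (default [als_panels()]).
#' @param thresholds [filter_thresholds()] for QC and rarity.
#' @param acmg [acmg_thresholds()] for the automatic evaluators.
#' @param fixed [fixed_profile()] for the manually reviewed criteria.
#' @param include_low_vus Passed to [actionability()].
#' @param register Optional register tibble (with `standard_pop`) for the
#'   incidence table.
#' @param probabilities Optional age-group actionable probabilities for the
#'   policy estimate; defaults to the pipeline's own yield for
#'   `policy_panel` when a register is supplied.
#' @param policy [policy_config()] for the policy estimate.
#' @param policy_panel Which panel's yield feeds the policy estimate when
#'   `probabilities` is not given.
#' @param seed Seed recorded in the report header (the pipeline itself draws
#'   no random numbers).
#' @return A list of class `als_report`: `meta` (seed, config hash,
#'   stage-wise counts), `sample_qc`, `variant_audit`, `classified`,
#'   `repeats`, `actionability`, `yield`, and optionally `incidence` and
#'   `missed`.
#' @export
run_pipeline <- function(cohort,
                         panels = als_panels(),
                         thresholds = filter_thresholds(),
                         acmg = acmg_thresholds(),
                         fixed = fixed_profile("conservative"),
                         include_low_vus = FALSE,
                         register = NULL,
                         probabilities = NULL,
                         policy = policy_config(),
                         policy_panel = "genomics_england",
                         seed = NULL) {
  stage <- "sample_qc"
  report <- tryCatch(
    {
      n_input <- nrow(cohort$persons)
      if (n_input >= 2) {
        qc <- filter_samples(cohort$sample_metrics, thresholds)
        kept <- qc$person_id[qc$keep]
      } else {
        qc <- tibble()
        kept <- cohort$persons$person_id
      }
      persons <- cohort$persons %>% filter(.data$person_id %in% kept)
      variants <- cohort$variants %>% filter(.data$person_id %in% kept)
      repeats_in <- cohort$repeat_calls %>%
        filter(.data$person_id %in% kept)

      stage <- "prioritise"
      prioritised <- prioritise_variants(variants, thresholds)
      audit <- attr(prioritised, "audit")

      stage <- "acmg"
      classified <- classify_variants(prioritised,
        fixed = fixed, thresholds = acmg
      )

      stage <- "repeats"
      repeats <- if (nrow(repeats_in) > 0) {
        interpret_repeats(repeats_in)
      } else {
        mutate(repeats_in,
          pathogenic = logical(0), note = character(0)
        )
      }

      stage <- "actionability"
      act <- actionability(classified, repeats, persons,
        panels = panels, include_low_vus = include_low_vus
      )

      stage <- "yield"
      yield <- if (nrow(persons) > 0) {
        yield_table(act, persons)
      } else {
        tibble(
          panel = character(),
          age_group = factor(character(), levels = age_group_levels()),
          n = integer(), k = integer(),
          p = double(), lower = double(), upper = double()
        )
      }

      incidence <- NULL
      missed <- NULL
      if (!is.null(register)) {
        stage <- "incidence"
        incidence <- incidence_table(register, policy)
        probs <- probabilities
        if (is.null(probs)) {
          probs <- yield %>%
            filter(.data$panel == policy_panel) %>%
            transmute(age_group = as.character(.data$age_group), p = .data$p)
        }
        stage <- "policy"
        missed <- missed_estimate(incidence, probs, policy)
      }

      config_hash <- hash(list(
        thresholds = unclass(thresholds), acmg = unclass(acmg),
        fixed = unclass(fixed), panels = panels,
        include_low_vus = include_low_vus, policy = unclass(policy)
      ))
      counts <- list(
        persons_in = n_input,
        persons_retained = nrow(persons),
        variants_in = nrow(variants),
        variants_retained = nrow(prioritised),
        removed = if (nrow(audit) > 0) {
          stats::setNames(as.list(audit$n), audit$reason)
        } else {
          list()
        },
        actionable = act %>%
          group_by(.data$panel) %>%
          summarise(k = sum(.data$actionable), .groups = "drop")
      )
      structure(
        list(
          meta = list(
            seed = seed, config_hash = config_hash, counts = counts
          ),
          sample_qc = qc, variant_audit = audit, classified = classified,
          repeats = repeats, actionability = act, yield = yield,
          incidence = incidence, missed = missed
        ),
        class = "als_report"
      )
    },
    error = function(e) {
      abort(
        paste0("Pipeline failed at stage '", stage, "': ", conditionMessage(e)),
        class = "alsyield_pipeline_error", parent = e
      )
    }
  )
  report
}

#' @method print als_report
#' @export
print.als_report <- function(x, ...) {
  cnt <- x$meta$counts
  cat("ALS actionability pipeline report\n")
  cat(
    "  persons: ", cnt$persons_retained, "/", cnt$persons_in,
    " retained after sample QC\n",
    sep = ""
  )
  cat(
    "  variants: ", cnt$variants_retained, "/", cnt$variants_in,
    " retained after prioritisation\n",
    sep = ""
  )
  if (nrow(cnt$actionable) > 0) {
    for (i in seq_len(nrow(cnt$actionable))) {
      cat(
        "  actionable (", cnt$actionable$panel[i], "): ",
        cnt$actionable$k[i], "\n",
        sep = ""
      )
    }
  }
  if (!is.null(x$missed)) print(x$missed)
  invisible(x)
}

#' @method tidy als_report
#' @export
tidy.als_report <- function(x, ...) {
  tidy(x$yield)
}

#' @method glance als_report
#' @export
glance.als_report <- function(x, ...) {
  cnt <- x$meta$counts
  tibble(
    persons_in = cnt$persons_in,
    persons_retained = cnt$persons_retained,
    variants_in = cnt$variants_in,
    variants_retained = cnt$variants_retained
  )
}

#' Serialize a pipeline report to canonical JSON
#'
#' A stable, text-only rendering of the report's headline content (meta with
#' seed and config hash, QC counts, yield table, policy estimate), suitable
#' for regression comparison byte-for-byte.
#'
#' @param report An `als_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    meta = report$meta,
    yield = as_tibble(unclass(report$yield)) %>%
      mutate(age_group = as.character(.data$age_group)),
    actionability = as_tibble(unclass(report$actionability))
  )
  if (!is.null(report$missed)) {
    payload$missed <- glance(report$missed)
  }
  json <- jsonlite::toJSON(payload,
    dataframe = "rows", auto_unbox = TRUE, digits = 10, na = "null",
    pretty = TRUE
  )
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
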