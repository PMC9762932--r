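# ACMG/AMP 28-criterion classification engine:
# automatic evaluators + fixed-value profiles + published combining rules
# + sub-stratification of variants of uncertain significance.

#' Names of the 28 ACMG/AMP evidence criteria
#'
#' 16 pathogenicity criteria (PVS1; PS1-PS4; PM1-PM6; PP1-PP5) and 12
#' benignity criteria (BA1; BS1-BS4; BP1-BP7), in canonical order.
#'
#' @return Character vector of length 28.
#' @export
acmg_criteria <- function() {
  c(
    "PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7)
  )
}

PATHOGENIC_CRITERIA <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5))
BENIGN_CRITERIA <- c("BA1", paste0("BS", 1:4), paste0("BP", 1:7))

# criteria with an automatic evaluator in auto_evidence(); everything else is
# fixed-value only (set through a fixed profile)
AUTO_CRITERIA <- c("PVS1", "PM2", "PM4", "BA1", "BS1", "PP3", "BP4")

ACMG_CLASS_LEVELS <- c(
  "benign", "likely_benign", "vus", "likely_pathogenic", "pathogenic"
)

#' Numeric thresholds and gene lists for the automatic ACMG evaluators
#'
#' Configuration for the criteria that can be evaluated from the annotation
#' fields alone. Defaults: `PM2` requires allele frequency below `1e-4` in
#' both reference sets; `BA1` fires above 5% external frequency (the standard
#' stand-alone benign cut); `BS1` above the disease-based cut (default 0.001,
#' the reporting rarity bound: anything commoner is too frequent for a rare
#' dominant ALS allele); `PP3`/`BP4` compare a scaled in-silico deleteriousness
#' score in `[0, 1]` against 0.7 / 0.15. `lof_genes` lists genes for which
#' loss of function is an accepted disease mechanism, enabling `PVS1` for
#' high-impact variants.
#'
#' @param pm2_max_af Strict bound for PM2 (absent/ultra-rare), both sets.
#' @param ba1_min_af Stand-alone benign frequency cut (exclusive).
#' @param bs1_min_af Frequency-greater-than-expected cut (exclusive).
#' @param pp3_min_score Minimum in-silico score supporting pathogenicity.
#' @param bp4_max_score Maximum in-silico score supporting a benign call.
#' @param lof_genes Character vector of loss-of-function-mechanism genes.
#' @return A list of class `als_acmg_thresholds`.
#' @export
acmg_thresholds <- function(pm2_max_af = 1e-4,
                            ba1_min_af = 0.05,
                            bs1_min_af = 0.001,
                            pp3_min_score = 0.7,
                            bp4_max_score = 0.15,
                            lof_genes = c(
                              "ALS2", "FIG4", "OPTN", "SPG11", "TBK1"
                            )) {
  check_prob(c(pm2_max_af, ba1_min_af, bs1_min_af), "frequency cuts")
  structure(
    list(
      pm2_max_af = pm2_max_af, ba1_min_af = ba1_min_af,
      bs1_min_af = bs1_min_af, pp3_min_score = pp3_min_score,
      bp4_max_score = bp4_max_score, lof_genes = lof_genes
    ),
    class = "als_acmg_thresholds"
  )
}

#' Automatically evaluable ACMG evidence
#'
#' Computes, from the annotation fields alone, the criteria that have an
#' automatic evaluator: `PVS1` (high impact in a loss-of-function-mechanism
#' gene), `PM2` (absent or ultra-rare in both reference sets), `PM4`
#' (in-frame length change or stop lost), `BA1`/`BS1` (frequency above the
#' stand-alone / disease-based cut), and `PP3`/`BP4` (in-silico score beyond
#' the deleterious / benign cut). All other criteria are `FALSE` at this
#' stage. A missing in-silico score leaves `PP3` and `BP4` `FALSE`.
#'
#' @param variants Prioritised variant tibble carrying `gene`, `impact`,
#'   `af_reference`, `af_internal`, `consequence_terms` and optionally
#'   `insilico_score`.
#' @param thresholds An [acmg_thresholds()] object.
#' @param verbose Log a note when score-based criteria defaulted to `FALSE`
#'   for lack of a score.
#' @return Tibble with 28 logical columns named after [acmg_criteria()],
#'   row-aligned with `variants`.
#' @export
auto_evidence <- function(variants, thresholds = acmg_thresholds(),
                          verbose = FALSE) {
  check_columns(
    variants,
    c("gene", "impact", "af_reference", "af_internal", "consequence_terms"),
    "prioritised variant table"
  )
  n <- nrow(variants)
  ev <- as.data.frame(matrix(FALSE, n, 28,
    dimnames = list(NULL, acmg_criteria())
  ))
  if (n == 0) {
    return(as_tibble(ev))
  }
  score <- if ("insilico_score" %in% names(variants)) {
    variants$insilico_score
  } else {
    rep(NA_real_, n)
  }
  has_term <- function(terms) {
    vapply(
      strsplit(as.character(variants$consequence_terms), "[&,]"),
      function(tt) any(tt %in% terms), TRUE
    )
  }
  ev$PVS1 <- variants$impact == "high" & variants$gene %in% thresholds$lof_genes
  ev$PM2 <- variants$af_reference < thresholds$pm2_max_af &
    variants$af_internal < thresholds$pm2_max_af
  ev$PM4 <- has_term(c("inframe_insertion", "inframe_deletion", "stop_lost"))
  ev$BA1 <- variants$af_reference > thresholds$ba1_min_af
  ev$BS1 <- variants$af_reference > thresholds$bs1_min_af
  ev$PP3 <- !is.na(score) & score >= thresholds$pp3_min_score
  ev$BP4 <- !is.na(score) & score <= thresholds$bp4_max_score
  if (verbose && anyNA(score)) {
    message(
      sum(is.na(score)),
      " variant(s) had no in-silico score; PP3/BP4 left unset for them."
    )
  }
  as_tibble(ev)
}

#' Fixed-value profiles for the manually reviewed ACMG criteria
#'
#' In routine curation, the criteria without an automatic evaluator require
#' per-variant literature review; at cohort scale this is approximated by
#' forcing each such criterion to a predefined value per impact class. Two
#' documented profiles ship with the package:
#'
#' * `"conservative"` — every non-automatic criterion is forced `FALSE` for
#'   both impact classes; classifications rest on the automatic evidence only.
#' * `"permissive"` — as conservative, but the non-automatic supporting
#'   criteria (PP1, PP2, PP4, PP5) are forced `TRUE` for high-impact
#'   variants, moving well-supported loss-of-function variants up a class.
#'
#' The choice is a sensitivity parameter: results should be reported under a
#' stated profile. Custom profiles can set any criterion to `"true"`,
#' `"false"` or `"auto"` (keep the automatic evaluator's value; only valid for
#' criteria that have one).
#'
#' @param name `"conservative"` or `"permissive"`, or `NULL` when supplying
#'   `high`/`moderate` directly.
#' @param high,moderate Optional named character vectors
#'   (criterion -> `"true"|"false"|"auto"`) overriding the named profile for
#'   that impact class.
#' @return A list of class `als_fixed_profile` with elements `high` and
#'   `moderate`, each a full 28-entry named vector.
#' @export
fixed_profile <- function(name = c("conservative", "permissive"),
                          high = NULL, moderate = NULL) {
  base <- stats::setNames(
    ifelse(acmg_criteria() %in% AUTO_CRITERIA, "auto", "false"),
    acmg_criteria()
  )
  prof <- list(high = base, moderate = base)
  if (!is.null(name)) {
    name <- match.arg(name)
    if (name == "permissive") {
      prof$high[c("PP1", "PP2", "PP4", "PP5")] <- "true"
    }
  }
  apply_over <- function(current, override, label) {
    if (is.null(override)) {
      return(current)
    }
    bad <- setdiff(names(override), acmg_criteria())
    if (length(bad) > 0) {
      stop_config(paste0(
        "Unknown criterion name(s) in fixed profile (", label, "): ",
        paste(bad, collapse = ", ")
      ))
    }
    if (!all(override %in% c("true", "false", "auto"))) {
      stop_config("Fixed-profile values must be 'true', 'false' or 'auto'.")
    }
    auto_bad <- names(override)[override == "auto" &
      !names(override) %in% AUTO_CRITERIA]
    if (length(auto_bad) > 0) {
      stop_config(paste0(
        "Criteria without an automatic evaluator cannot be 'auto': ",
        paste(auto_bad, collapse = ", ")
      ))
    }
    current[names(override)] <- override
    current
  }
  prof$high <- apply_over(prof$high, high, "high")
  prof$moderate <- apply_over(prof$moderate, moderate, "moderate")
  structure(prof, class = "als_fixed_profile")
}

#' Merge automatic evidence with a fixed-value profile
#'
#' For each criterion, a forced `"true"`/`"false"` in the profile keyed by the
#' variant's impact class overrides the automatic value; `"auto"` keeps it.
#' The result is a complete 28-flag evidence profile per variant.
#'
#' @param evidence Tibble of 28 logical columns from [auto_evidence()].
#' @param fixed A [fixed_profile()] object.
#' @param impact Factor/character vector (`high`/`moderate`), row-aligned.
#' @return Tibble of 28 logical columns.
#' @export
merge_fixed <- function(evidence, fixed, impact) {
  if (!inherits(fixed, "als_fixed_profile")) {
    stop_config("`fixed` must be created by fixed_profile().")
  }
  check_columns(evidence, acmg_criteria(), "evidence profile")
  impact <- as.character(impact)
  is_high <- impact == "high"
  out <- evidence
  for (crit in acmg_criteria()) {
    fh <- fixed$high[[crit]]
    fm <- fixed$moderate[[crit]]
    v <- out[[crit]]
    v[is_high & fh != "auto"] <- (fh == "true")
    v[!is_high & fm != "auto"] <- (fm == "true")
    out[[crit]] <- v
  }
  out
}

acmg_counts <- function(evidence) {
  as_mat <- function(cols) {
    as.matrix(evidence[, cols, drop = FALSE])
  }
  list(
    pvs1 = evidence$PVS1,
    ps = rowSums(as_mat(paste0("PS", 1:4))),
    pm = rowSums(as_mat(paste0("PM", 1:6))),
    pp = rowSums(as_mat(paste0("PP", 1:5))),
    ba1 = evidence$BA1,
    bs = rowSums(as_mat(paste0("BS", 1:4))),
    bp = rowSums(as_mat(paste0("BP", 1:7))),
    n_path = rowSums(as_mat(PATHOGENIC_CRITERIA)),
    n_ben = rowSums(as_mat(BENIGN_CRITERIA))
  )
}

#' Combine a 28-flag evidence profile into an ACMG class
#'
#' Implements the published combining rules. Pathogenic: PVS1 with (>=1 PS,
#' >=2 PM, 1 PM + 1 PP, or >=2 PP); >=2 PS; or 1 PS with (>=3 PM,
#' 2 PM + >=2 PP, or 1 PM + >=4 PP). Likely pathogenic: PVS1 + 1 PM;
#' 1 PS + 1-2 PM; 1 PS + >=2 PP; >=3 PM; 2 PM + >=2 PP; or 1 PM + >=4 PP.
#' Benign: BA1 alone, or >=2 BS. Likely benign: 1 BS + 1 BP, or >=2 BP.
#' Anything matching no rule — or matching rules on both sides
#' (contradictory evidence) — is a variant of uncertain significance.
#'
#' @param evidence Tibble/data frame with the 28 logical criterion columns.
#' @return Ordered factor with levels benign < likely_benign < vus <
#'   likely_pathogenic < pathogenic.
#' @export
acmg_combine <- function(evidence) {
  check_columns(evidence, acmg_criteria(), "evidence profile")
  cnt <- acmg_counts(evidence)
  path_p <- (cnt$pvs1 & (cnt$ps >= 1 | cnt$pm >= 2 |
    (cnt$pm >= 1 & cnt$pp >= 1) | cnt$pp >= 2)) |
    cnt$ps >= 2 |
    (cnt$ps >= 1 & (cnt$pm >= 3 |
      (cnt$pm >= 2 & cnt$pp >= 2) |
      (cnt$pm >= 1 & cnt$pp >= 4)))
  path_lp <- (cnt$pvs1 & cnt$pm >= 1) |
    (cnt$ps >= 1 & cnt$pm >= 1) |
    (cnt$ps >= 1 & cnt$pp >= 2) |
    cnt$pm >= 3 |
    (cnt$pm >= 2 & cnt$pp >= 2) |
    (cnt$pm >= 1 & cnt$pp >= 4)
  ben_b <- cnt$ba1 | cnt$bs >= 2
  ben_lb <- (cnt$bs >= 1 & cnt$bp >= 1) | cnt$bp >= 2
  pside <- path_p | path_lp
  bside <- ben_b | ben_lb
  cls <- dplyr::case_when(
    pside & bside ~ "vus",
    path_p ~ "pathogenic",
    path_lp ~ "likely_pathogenic",
    ben_b ~ "benign",
    ben_lb ~ "likely_benign",
    TRUE ~ "vus"
  )
  factor(cls, levels = ACMG_CLASS_LEVELS, ordered = TRUE)
}

#' Sub-stratify variants of uncertain significance
#'
#' A VUS is of `high` probability of pathogenicity when it matches at least
#' one of the 16 pathogenicity criteria and none of the 12 benignity criteria,
#' and of `low_medium` probability otherwise. Non-VUS classes map to
#' `not_applicable`.
#'
#' @inheritParams acmg_combine
#' @param acmg_class Factor/character vector of classes, row-aligned with
#'   `evidence` (from [acmg_combine()]).
#' @return Factor with levels `high`, `low_medium`, `not_applicable`.
#' @export
stratify_vus <- function(evidence, acmg_class) {
  check_columns(evidence, acmg_criteria(), "evidence profile")
  cnt <- acmg_counts(evidence)
  sub <- dplyr::case_when(
    acmg_class != "vus" ~ "not_applicable",
    cnt$n_path >= 1 & cnt$n_ben == 0 ~ "high",
    TRUE ~ "low_medium"
  )
  factor(sub, levels = c("high", "low_medium", "not_applicable"))
}

#' Classify prioritised variants under the ACMG framework
#'
#' Convenience wrapper running [auto_evidence()], [merge_fixed()],
#' [acmg_combine()] and [stratify_vus()] over a prioritised variant table,
#' appending the 28 evidence flags, `acmg_class` and `vus_subclass`.
#'
#' @param variants Prioritised variant tibble (must carry `impact`; see
#'   [prioritise_variants()]).
#' @param fixed A [fixed_profile()] (default `"conservative"`).
#' @param thresholds An [acmg_thresholds()] object.
#' @param verbose Passed to [auto_evidence()].
#' @return The input tibble with 30 columns appended.
#' @export
classify_variants <- function(variants, fixed = fixed_profile("conservative"),
                              thresholds = acmg_thresholds(),
                              verbose = FALSE) {
  check_columns(variants, "impact", "prioritised variant table")
  ev <- auto_evidence(variants, thresholds, verbose = verbose)
  ev <- merge_fixed(ev, fixed, variants$impact)
  cls <- acmg_combine(ev)
  sub <- stratify_vus(ev, cls)
  bind_cols(as_tibble(variants), ev) %>%
    mutate(acmg_class = cls, vus_subclass = sub)
}
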