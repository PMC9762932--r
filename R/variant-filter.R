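# site/sample QC and rarity/impact prioritisation of annotated variants

# sequence-ontology consequence terms by predicted functional impact
HIGH_IMPACT_TERMS <- c(
  "stop_gained", "stop_lost", "start_lost", "transcript_amplification",
  "transcript_ablation", "frameshift_variant", "splice_acceptor_variant",
  "splice_donor_variant"
)
MODERATE_IMPACT_TERMS <- c(
  "missense_variant", "inframe_insertion", "inframe_deletion",
  "protein_altering_variant"
)

#' Filtering thresholds for variant and sample QC
#'
#' Container for the quality-control and rarity thresholds applied before any
#' classification. Defaults follow standard short-read WGS reporting practice:
#' genotype quality below 10 removed, site quality below 20 (SNV) or 30
#' (indel) removed, per-variant missingness above 2% removed, minor allele
#' frequency must be below 0.001 in *both* reference sets, and sample-level
#' metrics must lie within mean +/- 6 SD of the full sample distribution.
#'
#' @param min_genotype_quality Minimum genotype quality retained (default 10).
#' @param min_snv_quality Minimum site quality for SNVs (default 20).
#' @param min_indel_quality Minimum site quality for indels (default 30).
#' @param max_missingness Maximum per-variant missingness retained
#'   (default 0.02).
#' @param max_af Strict upper bound on allele frequency in each reference set
#'   (default 0.001).
#' @param sd_multiplier Width of the sample-metric outlier interval in
#'   standard deviations (default 6).
#' @return A list of class `als_filter_thresholds`.
#' @export
filter_thresholds <- function(min_genotype_quality = 10,
                              min_snv_quality = 20,
                              min_indel_quality = 30,
                              max_missingness = 0.02,
                              max_af = 0.001,
                              sd_multiplier = 6) {
  vals <- c(
    min_genotype_quality, min_snv_quality, min_indel_quality,
    max_missingness, max_af, sd_multiplier
  )
  if (any(!is.finite(vals) | vals < 0)) {
    stop_config("All filter thresholds must be non-negative numbers.")
  }
  structure(
    list(
      min_genotype_quality = min_genotype_quality,
      min_snv_quality = min_snv_quality,
      min_indel_quality = min_indel_quality,
      max_missingness = max_missingness,
      max_af = max_af,
      sd_multiplier = sd_multiplier
    ),
    class = "als_filter_thresholds"
  )
}

#' Predicted functional impact of a variant's consequence terms
#'
#' Classifies a set of sequence-ontology consequence terms into `high`,
#' `moderate` or `low_or_other` by the most severe term present. High-impact
#' terms are stop gained/lost, start lost, transcript amplification/ablation,
#' frameshift, and splice acceptor/donor; moderate-impact terms are missense,
#' in-frame insertion/deletion and protein-altering.
#'
#' @param consequence_terms Character vector; each element may carry several
#'   terms separated by `&` or `,` (as annotation tools emit them).
#' @return Factor with levels `high`, `moderate`, `low_or_other`.
#' @examples
#' impact_class(c("missense_variant", "frameshift_variant&missense_variant"))
#' @export
impact_class <- function(consequence_terms) {
  if (length(consequence_terms) == 0) {
    stop_input("`consequence_terms` must be non-empty.")
  }
  terms <- strsplit(as.character(consequence_terms), "[&,]")
  if (any(vapply(terms, function(x) length(x) == 0 || all(!nzchar(x)), TRUE)) ||
    any(is.na(consequence_terms))) {
    stop_input("Every variant must carry at least one consequence term.")
  }
  cls <- vapply(terms, function(tt) {
    if (any(tt %in% HIGH_IMPACT_TERMS)) "high"
    else if (any(tt %in% MODERATE_IMPACT_TERMS)) "moderate"
    else "low_or_other"
  }, character(1))
  factor(cls, levels = c("high", "moderate", "low_or_other"))
}

#' Site-level quality filter
#'
#' Keeps a variant iff genotype quality, site quality (SNV/indel specific) and
#' missingness all pass. Removal conditions are strict (`GQ < 10`,
#' `qual < 20/30`, `missingness > 2%`), so boundary values are retained.
#'
#' @param variants Data frame with columns `variant_class`, `site_quality`,
#'   `genotype_quality`, `missingness`.
#' @param thresholds A [filter_thresholds()] object.
#' @return Logical vector, `TRUE` for variants passing site QC.
#' @export
site_filter <- function(variants, thresholds = filter_thresholds()) {
  check_columns(
    variants,
    c("variant_class", "site_quality", "genotype_quality", "missingness"),
    "variant table"
  )
  min_qual <- ifelse(variants$variant_class == "SNV",
    thresholds$min_snv_quality, thresholds$min_indel_quality
  )
  variants$genotype_quality >= thresholds$min_genotype_quality &
    variants$site_quality >= min_qual &
    variants$missingness <= thresholds$max_missingness
}

#' Rarity filter over two reference frequency sets
#'
#' A variant is retained only when its allele frequency is strictly below
#' `max_af` in *both* the external reference (non-Finnish European) and the
#' internal control set.
#'
#' @param af_reference,af_internal Numeric vectors of allele frequencies
#'   in `[0, 1]`.
#' @inheritParams site_filter
#' @return Logical vector.
#' @export
rarity_filter <- function(af_reference, af_internal,
                          thresholds = filter_thresholds()) {
  check_prob(af_reference, "af_reference")
  check_prob(af_internal, "af_internal")
  af_reference < thresholds$max_af & af_internal < thresholds$max_af
}

#' Sample-level quality filter
#'
#' Flags samples whose Ti/Tv ratio, SNV, indel or singleton counts fall
#' outside mean +/- `sd_multiplier` SD of the full input distribution
#' (computed once, not iteratively), whose genetically inferred sex
#' contradicts the reported sex, or whose age of onset is missing. An
#' `unknown` sex on either side is not a contradiction. Drop reasons are
#' attributed in the fixed order metric outlier, sex mismatch, missing age.
#'
#' @param metrics Data frame with columns `person_id`, `titv`, `n_snv`,
#'   `n_indel`, `n_singleton`, `inferred_sex`, `reported_sex`, `age_onset`.
#' @inheritParams site_filter
#' @return The input tibble with logical `keep` and character `drop_reason`
#'   (`NA` for retained samples) appended.
#' @export
filter_samples <- function(metrics, thresholds = filter_thresholds()) {
  check_columns(metrics, c(
    "person_id", "titv", "n_snv", "n_indel", "n_singleton",
    "inferred_sex", "reported_sex", "age_onset"
  ), "sample metrics")
  if (nrow(metrics) < 2) {
    stop_input("Sample filtering needs at least 2 samples to define an SD.")
  }
  k <- thresholds$sd_multiplier
  outlier <- rep(FALSE, nrow(metrics))
  for (col in c("titv", "n_snv", "n_indel", "n_singleton")) {
    x <- metrics[[col]]
    m <- mean(x)
    s <- sd(x)
    outlier <- outlier | abs(x - m) > k * s
  }
  known <- metrics$inferred_sex != "unknown" & metrics$reported_sex != "unknown"
  sex_mismatch <- known & metrics$inferred_sex != metrics$reported_sex
  no_age <- is.na(metrics$age_onset)
  reason <- dplyr::case_when(
    outlier ~ "metric_outlier",
    sex_mismatch ~ "sex_mismatch",
    no_age ~ "missing_age",
    TRUE ~ NA_character_
  )
  metrics %>%
    mutate(keep = is.na(reason), drop_reason = reason) %>%
    as_tibble()
}

#' Retained person ids after sample QC
#'
#' Convenience wrapper around [filter_samples()] returning the ids of samples
#' that pass all sample-level checks.
#'
#' @inheritParams filter_samples
#' @return Character vector of retained `person_id`s.
#' @export
sample_filter <- function(metrics, thresholds = filter_thresholds()) {
  flagged <- filter_samples(metrics, thresholds)
  flagged$person_id[flagged$keep]
}

#' Prioritise reportable variants
#'
#' Applies, in a fixed order, site QC, the two-reference rarity rule and the
#' moderate/high impact requirement, and appends the computed impact class.
#' Each removed variant is attributed to the first failing rule
#' (QC, then frequency, then impact), so audit counts always sum to the input.
#'
#' @param variants Annotated variant data frame (one row per person-variant).
#' @inheritParams site_filter
#' @param keep_all If `TRUE`, return all rows with `impact`, `retained` and
#'   `drop_reason` columns; if `FALSE` (default) return only retained rows
#'   (plus `impact`), with the removal audit in `attr(., "audit")`.
#' @return A tibble; see `keep_all`.
#' @export
prioritise_variants <- function(variants, thresholds = filter_thresholds(),
                                keep_all = FALSE) {
  check_columns(
    variants, c("af_reference", "af_internal", "consequence_terms"),
    "variant table"
  )
  if (nrow(variants) == 0) {
    out <- as_tibble(variants) %>%
      mutate(
        impact = factor(character(), c("high", "moderate", "low_or_other"))
      )
    if (keep_all) {
      return(mutate(out, retained = logical(), drop_reason = character()))
    }
    attr(out, "audit") <- tibble(
      reason = character(), n = integer()
    )
    return(out)
  }
  pass_qc <- site_filter(variants, thresholds)
  pass_freq <- rarity_filter(
    variants$af_reference, variants$af_internal, thresholds
  )
  impact <- impact_class(variants$consequence_terms)
  pass_impact <- impact %in% c("high", "moderate")
  reason <- dplyr::case_when(
    !pass_qc ~ "site_qc",
    !pass_freq ~ "frequency",
    !pass_impact ~ "impact",
    TRUE ~ NA_character_
  )
  out <- as_tibble(variants) %>%
    mutate(impact = impact, retained = is.na(reason), drop_reason = reason)
  if (keep_all) {
    return(out)
  }
  audit <- out %>%
    filter(!.data$retained) %>%
    count(reason = .data$drop_reason, name = "n")
  res <- out %>%
    filter(.data$retained) %>%
    select(-"retained", -"drop_reason")
  attr(res, "audit") <- audit
  res
}
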