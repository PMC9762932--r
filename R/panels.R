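# gene panels, inheritance-mode reporting logic, per-person actionability,
# and the database corroboration rule for the four-gene panel

FOUR_GENE_PANEL <- c("C9orf72", "FUS", "SOD1", "TARDBP")
LARGER_PANEL <- c(
  "ANG", "ATXN2", "C21orf2", "C9orf72", "CHCHD10", "DAO", "DCTN1", "FUS",
  "HNRNPA1", "MATR3", "MOBP", "NEK1", "OPTN", "PFN1", "SCFD1", "SOD1",
  "SQSTM1", "TAF15", "TARDBP", "TBK1", "TUB4A", "UBQLN2", "VAPB", "VCP"
)
GENOMICS_ENGLAND_PANEL <- c(
  "ALS2", "ANG", "ANXA11", "ATXN2", "C9orf72", "CHCHD10", "DCTN1", "ERBB4",
  "FIG4", "FUS", "HNRNPA1", "MATR3", "NEFH", "OPTN", "PFN1", "SETX",
  "SIGMAR1", "SOD1", "SPG11", "SQSTM1", "TARDBP", "TBK1", "TUB4A", "UBQLN2",
  "VAPB", "VCP"
)

#' Define a gene panel with per-gene reporting modes
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols.
#' @param biallelic_only Subset of `genes` reported only when both alleles are
#'   affected (homozygous genotype); all other genes are reportable from a
#'   single heterozygous (or hemizygous) variant.
#' @return Tibble with columns `panel`, `gene`, `reporting_mode`.
#' @export
panel_definition <- function(name, genes, biallelic_only = character()) {
  if (length(genes) == 0) stop_config("A panel needs at least one gene.")
  stray <- setdiff(biallelic_only, genes)
  if (length(stray) > 0) {
    stop_config(paste0(
      "biallelic_only gene(s) not in the panel: ", paste(stray, collapse = ", ")
    ))
  }
  tibble(
    panel = name, gene = genes,
    reporting_mode = ifelse(genes %in% biallelic_only,
      "biallelic_only", "het_reportable"
    )
  )
}

#' The shipped ALS gene panels
#'
#' Three panels reflecting common testing practice: the `four_gene` panel of
#' the commonest ALS genes (C9orf72, FUS, SOD1, TARDBP); a `larger` 24-gene
#' panel of rare large-effect Mendelian ALS genes; and a 26-gene
#' `genomics_england` panel used in UK practice, in which ALS2 — associated
#' with ALS only in homozygosity — is reported for bi-allelic variants only.
#'
#' @param names Which panels to return.
#' @return Tibble of panel definitions (see [panel_definition()]).
#' @export
als_panels <- function(names = c("four_gene", "larger", "genomics_england")) {
  names <- match.arg(names, several.ok = TRUE)
  defs <- list(
    four_gene = panel_definition("four_gene", FOUR_GENE_PANEL),
    larger = panel_definition("larger", LARGER_PANEL),
    genomics_england = panel_definition(
      "genomics_england", GENOMICS_ENGLAND_PANEL,
      biallelic_only = "ALS2"
    )
  )
  bind_rows(defs[names])
}

#' Is a classified variant actionable on its own?
#'
#' A variant contributes to a clinically actionable result when it has a
#' moderate or high predicted impact and is classified pathogenic or likely
#' pathogenic, or is a VUS of high probability of pathogenicity. With
#' `include_low_vus = TRUE`, low/medium-probability VUS also count (the
#' broader reading in which only benign and likely benign calls are excluded).
#'
#' @param acmg_class,vus_subclass,impact Row-aligned vectors as produced by
#'   [classify_variants()].
#' @param include_low_vus Count low/medium-probability VUS as actionable.
#' @return Logical vector.
#' @export
variant_actionable <- function(acmg_class, vus_subclass, impact,
                               include_low_vus = FALSE) {
  ok_impact <- impact %in% c("high", "moderate")
  plp <- acmg_class %in% c("pathogenic", "likely_pathogenic")
  vus_ok <- acmg_class == "vus" &
    (vus_subclass == "high" | include_low_vus)
  ok_impact & (plp | vus_ok)
}

#' Per-person, per-panel actionability
#'
#' Combines classified sequence variants and interpreted repeat calls into a
#' per-person actionability decision for each panel. A variant contributes
#' when [variant_actionable()] holds, its gene is on the panel, and the
#' panel's reporting mode is satisfied (`het_reportable`: any zygosity;
#' `biallelic_only`: homozygous genotype required — two heterozygous variants
#' are never combined, since phase is unknown). A pathogenic repeat call
#' contributes when its locus is on the panel. Every person in `persons`
#' appears in the output (the cohort denominator), actionable or not.
#'
#' @param classified Variant tibble from [classify_variants()].
#' @param repeats Repeat tibble from [interpret_repeats()] (or `NULL`).
#' @param persons Data frame with at least `person_id`.
#' @param panels Panel definition tibble (default [als_panels()]).
#' @inheritParams variant_actionable
#' @return Tibble of class `als_actionability` with columns `person_id`,
#'   `panel`, `actionable`, `n_contributors`; the contributor detail
#'   (variant/repeat, gene, reason) is in `attr(., "contributors")`.
#' @export
actionability <- function(classified, repeats, persons,
                          panels = als_panels(),
                          include_low_vus = FALSE) {
  check_columns(persons, "person_id", "persons")
  check_columns(panels, c("panel", "gene", "reporting_mode"), "panels")

  var_contrib <- tibble(
    person_id = character(), panel = character(), type = character(),
    gene = character(), reason = character()
  )
  if (!is.null(classified) && nrow(classified) > 0) {
    check_columns(
      classified,
      c("person_id", "gene", "zygosity", "impact", "acmg_class", "vus_subclass"),
      "classified variants"
    )
    var_contrib <- classified %>%
      filter(variant_actionable(
        .data$acmg_class, .data$vus_subclass, .data$impact, include_low_vus
      )) %>%
      inner_join(panels, by = "gene", relationship = "many-to-many") %>%
      filter(.data$reporting_mode == "het_reportable" |
        .data$zygosity == "homozygous") %>%
      transmute(.data$person_id, .data$panel,
        type = "variant", .data$gene,
        reason = as.character(.data$acmg_class)
      )
  }

  rep_contrib <- tibble(
    person_id = character(), panel = character(), type = character(),
    gene = character(), reason = character()
  )
  if (!is.null(repeats) && nrow(repeats) > 0) {
    check_columns(repeats, c("person_id", "gene", "pathogenic"), "repeats")
    rep_contrib <- repeats %>%
      filter(.data$pathogenic) %>%
      inner_join(panels, by = "gene", relationship = "many-to-many") %>%
      transmute(.data$person_id, .data$panel,
        type = "repeat", .data$gene,
        reason = "pathogenic_repeat"
      )
  }

  contributors <- bind_rows(var_contrib, rep_contrib)
  res <- expand_grid(
    person_id = persons$person_id, panel = unique(panels$panel)
  ) %>%
    left_join(
      count(contributors, .data$person_id, .data$panel),
      by = c("person_id", "panel")
    ) %>%
    mutate(
      n_contributors = dplyr::coalesce(.data$n, 0L),
      actionable = .data$n_contributors > 0
    ) %>%
    select("person_id", "panel", "actionable", "n_contributors")
  attr(res, "contributors") <- contributors
  class(res) <- c("als_actionability", class(res))
  res
}

#' Database corroboration rule for the four commonest ALS genes
#'
#' An alternative, database-driven definition of a reportable result used to
#' corroborate the automated classification: a C9orf72 repeat expansion above
#' 30; any retained rare SOD1 variant; and, for TARDBP and FUS, variants
#' either classified pathogenic/likely pathogenic in ClinVar or present in
#' the ALS online database with at least one publication and at least two
#' patients. Variants in other genes never qualify. Missing database flags
#' for a TARDBP/FUS variant yield `FALSE` with a warning.
#'
#' @param variants Prioritised (rare, moderate/high-impact) variant tibble
#'   with `gene` and the database flag columns `clinvar_plp`,
#'   `alsod_publications`, `alsod_patients`.
#' @return Logical vector, one element per variant row.
#' @export
corroboration_rule <- function(variants) {
  check_columns(variants, "gene", "variants")
  n <- nrow(variants)
  if (n == 0) {
    return(logical(0))
  }
  clin <- variants$clinvar_plp %||% rep(NA, n)
  pubs <- variants$alsod_publications %||% rep(NA_integer_, n)
  pats <- variants$alsod_patients %||% rep(NA_integer_, n)
  tf <- variants$gene %in% c("TARDBP", "FUS")
  if (any(tf & is.na(clin) & (is.na(pubs) | is.na(pats)))) {
    warn("TARDBP/FUS variant(s) with missing database flags treated as not corroborated.")
  }
  db_ok <- (!is.na(clin) & clin) |
    (!is.na(pubs) & !is.na(pats) & pubs >= 1 & pats >= 2)
  dplyr::case_when(
    variants$gene == "SOD1" ~ TRUE,
    tf ~ db_ok,
    TRUE ~ FALSE
  )
}

#' Per-person actionability under the corroboration definition
#'
#' Applies [corroboration_rule()] to the retained variants plus the C9orf72
#' repeat clause, giving a person-level decision comparable with the
#' ACMG-based four-gene panel result.
#'
#' @param variants Prioritised variant tibble (see [corroboration_rule()]).
#' @param repeats Interpreted repeat tibble (see [interpret_repeats()]).
#' @param persons Data frame with `person_id`.
#' @return Tibble `person_id`, `actionable`.
#' @export
corroboration_actionability <- function(variants, repeats, persons) {
  hits <- character()
  if (!is.null(variants) && nrow(variants) > 0) {
    hits <- c(hits, variants$person_id[corroboration_rule(variants)])
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    hits <- c(hits, repeats$person_id[
      repeats$gene == "C9orf72" & repeats$repeat_count > 30
    ])
  }
  tibble(
    person_id = persons$person_id,
    actionable = persons$person_id %in% hits
  )
}
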