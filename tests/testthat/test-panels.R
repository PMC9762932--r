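classify_one <- function(v) {
  classify_variants(prioritise_variants(v))
}

person_tbl <- function(ids) tibble::tibble(person_id = ids)

test_that("a single heterozygous pathogenic variant is reportable except in biallelic-only genes", {
  sod1 <- classify_one(make_variant(
    gene = "SOD1", consequence_terms = "missense_variant",
    insilico_score = 0.9
  )) # PM2 + PP3 -> VUS high: actionable
  act <- actionability(sod1, NULL, person_tbl("P1"))
  expect_true(all(act$actionable))

  als2_het <- classify_one(make_variant(
    gene = "ALS2", consequence_terms = "frameshift_variant",
    variant_class = "indel"
  )) # PVS1 + PM2 -> likely pathogenic
  expect_equal(as.character(als2_het$acmg_class), "likely_pathogenic")
  act_het <- actionability(als2_het, NULL, person_tbl("P1"))
  expect_false(any(act_het$actionable)) # het in a biallelic-only gene

  als2_hom <- als2_het
  als2_hom$zygosity <- "homozygous"
  act_hom <- actionability(als2_hom, NULL, person_tbl("P1"))
  expect_equal(
    act_hom$actionable[act_hom$panel == "genomics_england"], TRUE
  )
  # ALS2 is only on the Genomics England panel
  expect_false(any(act_hom$actionable[act_hom$panel != "genomics_england"]))
})

test_that("pathogenic repeats drive actionability panel-appropriately", {
  c9 <- interpret_repeats(tibble::tibble(
    person_id = "P1", gene = "C9orf72", repeat_count = 45
  ))
  act <- actionability(NULL, c9, person_tbl("P1"))
  expect_true(all(act$actionable)) # C9orf72 is on every shipped panel

  atxn2 <- interpret_repeats(tibble::tibble(
    person_id = "P1", gene = "ATXN2", repeat_count = 30
  ))
  act2 <- actionability(NULL, atxn2, person_tbl("P1")) %>%
    dplyr::arrange(panel)
  # intermediate ATXN2 counts only where ATXN2 is a panel gene
  expect_equal(act2$panel, c("four_gene", "genomics_england", "larger"))
  expect_equal(act2$actionable, c(FALSE, TRUE, TRUE))
})

test_that("low/medium VUS are excluded by default but included behind the switch", {
  vus_low <- classify_one(make_variant(
    gene = "SOD1", insilico_score = 0.05
  )) # PM2 + BP4 -> VUS low_medium
  expect_equal(as.character(vus_low$vus_subclass), "low_medium")
  expect_false(any(actionability(vus_low, NULL, person_tbl("P1"))$actionable))
  expect_true(all(actionability(vus_low, NULL, person_tbl("P1"),
    include_low_vus = TRUE
  )$actionable))

  lb <- classify_one(make_variant(gene = "SOD1", af_reference = 0.0009,
    af_internal = 0.0009, insilico_score = 0.05))
  expect_false(any(variant_actionable(lb$acmg_class, lb$vus_subclass, lb$impact)))
})

test_that("actionability is monotone over nested panels and empty input is not actionable", {
  # four_gene is a subset of the larger panel with identical reporting modes
  panels <- als_panels(c("four_gene", "larger"))
  cohort <- generate_cohort(cohort_config(n_persons = 250, seed = 7))
  cls <- classify_variants(prioritise_variants(cohort$variants))
  reps <- interpret_repeats(cohort$repeat_calls)
  act <- actionability(cls, reps, cohort$persons, panels = panels) %>%
    tidyr::pivot_wider(
      id_cols = "person_id", names_from = "panel", values_from = "actionable"
    )
  expect_true(all(!act$four_gene | act$larger))

  empty <- actionability(NULL, NULL, person_tbl(c("A", "B")))
  expect_false(any(empty$actionable))
  expect_equal(nrow(empty), 2 * length(unique(als_panels()$panel)))

  # actionable iff at least one contributor
  full <- actionability(cls, reps, cohort$persons)
  expect_equal(full$actionable, full$n_contributors > 0)
  contrib <- attr(full, "contributors")
  expect_setequal(
    unique(paste(contrib$person_id, contrib$panel)),
    paste(full$person_id, full$panel)[full$actionable]
  )
})

test_that("database corroboration reproduces the four-gene definition boundaries", {
  v <- dplyr::bind_rows(
    make_variant(gene = "SOD1"), # any retained rare SOD1 variant
    make_variant(
      gene = "FUS", clinvar_plp = FALSE,
      alsod_publications = 1L, alsod_patients = 2L
    ),
    make_variant(
      gene = "FUS", clinvar_plp = FALSE,
      alsod_publications = 3L, alsod_patients = 1L
    ), # below the >= 2 patients bar
    make_variant(gene = "TARDBP", clinvar_plp = TRUE),
    make_variant(gene = "TBK1", clinvar_plp = TRUE) # not a four-gene locus
  )
  expect_equal(corroboration_rule(v), c(TRUE, TRUE, FALSE, TRUE, FALSE))

  v_na <- make_variant(gene = "FUS")
  v_na$clinvar_plp <- NA
  v_na$alsod_publications <- NA_integer_
  expect_warning(ok <- corroboration_rule(v_na), "missing database flags")
  expect_false(ok)
})

test_that("ACMG route and corroboration route agree on a noise-free cohort", {
  cohort <- generate_cohort(noise_free_config(n_persons = 600, seed = 13))
  pri <- prioritise_variants(cohort$variants)
  cls <- classify_variants(pri)
  reps <- interpret_repeats(cohort$repeat_calls)
  acmg_route <- actionability(cls, reps, cohort$persons,
    panels = als_panels("four_gene")
  )
  db_route <- corroboration_actionability(pri, reps, cohort$persons)
  merged <- dplyr::inner_join(
    dplyr::select(acmg_route, "person_id", acmg = "actionable"),
    dplyr::select(db_route, "person_id", db = "actionable"),
    by = "person_id"
  )
  expect_equal(merged$acmg, merged$db)
})
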