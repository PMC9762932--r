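test_that("automatic evaluators fire on the documented annotation patterns", {
  v <- dplyr::bind_rows(
    make_variant(
      gene = "TBK1", consequence_terms = "frameshift_variant",
      variant_class = "indel"
    ), # high impact, LOF gene, absent
    make_variant(af_reference = 0.06, af_internal = 0.04),
    make_variant(insilico_score = 0.9),
    make_variant(insilico_score = 0.05),
    make_variant(consequence_terms = "stop_lost", gene = "SOD1"),
    make_variant() # no optional score: only PM2 can fire
  )
  v$impact <- impact_class(v$consequence_terms)
  ev <- auto_evidence(v)
  expect_true(ev$PVS1[1] && ev$PM2[1])
  expect_true(ev$BA1[2] && ev$BS1[2] && !ev$PM2[2])
  expect_true(ev$PP3[3])
  expect_true(ev$BP4[4])
  expect_true(ev$PM4[5] && !ev$PVS1[5]) # SOD1 not a LOF-mechanism gene
  expect_equal(sum(unlist(ev[6, ])), sum(ev$PM2[6]))
  # all non-automatic criteria stay FALSE here
  expect_true(all(!unlist(ev[, c("PS1", "PM1", "PP2", "BS2", "BP1")])))
})

test_that("fixed-value profiles override automatic evidence per impact class", {
  v <- make_variant(insilico_score = 0.9)
  v$impact <- impact_class(v$consequence_terms) # moderate
  ev <- auto_evidence(v)

  fx <- fixed_profile(NULL, moderate = c(PP2 = "true", PP3 = "false"))
  merged <- merge_fixed(ev, fx, v$impact)
  expect_true(merged$PP2[1]) # forced on regardless of auto
  expect_false(merged$PP3[1]) # forced off despite the score

  # a high-impact-only override leaves a moderate variant untouched
  fx2 <- fixed_profile(NULL, high = c(PM1 = "true"))
  expect_false(merge_fixed(ev, fx2, v$impact)$PM1[1])
  expect_true(merge_fixed(ev, fx2, "high")$PM1[1])

  # empty auto + all-auto/false profile: everything FALSE
  blank <- evidence_from_sets(list(character()))
  expect_false(any(unlist(merge_fixed(blank, fixed_profile(), "moderate"))))

  expect_error(
    fixed_profile(NULL, high = c(PX9 = "true")),
    class = "alsyield_config_error"
  )
  expect_error(
    fixed_profile(NULL, high = c(PS2 = "auto")), # PS2 has no evaluator
    class = "alsyield_config_error"
  )
})

test_that("combining rules give the published classes on worked profiles", {
  ev <- evidence_from_sets(list(
    character(), # nothing met
    "BA1", # stand-alone benign
    c("PVS1", "PM2"), # likely pathogenic
    c("PVS1", "PS1"), # pathogenic
    c("PVS1", "PM2", "PM4"), # pathogenic (PVS1 + 2 PM)
    c("PS1", "BS1", "BS2"), # PS1 completes no pathogenic rule: benign wins
    c("PVS1", "PS1", "BA1"), # both sides satisfied: contradiction
    c("BS1", "BP4"), # likely benign
    c("PM1", "PM2", "PM5") # 3 PM: likely pathogenic
  ))
  expect_equal(
    as.character(acmg_combine(ev)),
    c(
      "vus", "benign", "likely_pathogenic", "pathogenic", "pathogenic",
      "benign", "vus", "likely_benign", "likely_pathogenic"
    )
  )
})

test_that("VUS sub-stratification follows the pathogenic-only/no-benign rule", {
  ev <- evidence_from_sets(list(
    "PM2", # path evidence only -> high
    c("PM2", "BP4"), # benign flag present -> low_medium
    c("PVS1", "PM2"), # not a VUS
    character() # VUS with no flags -> low_medium
  ))
  cls <- acmg_combine(ev)
  sub <- stratify_vus(ev, cls)
  expect_equal(
    as.character(sub),
    c("high", "low_medium", "not_applicable", "low_medium")
  )
  # a high-probability VUS always carries at least one pathogenicity flag
  n_path <- rowSums(ev[, c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
    paste0("PP", 1:5))])
  expect_true(all(n_path[sub == "high"] >= 1))
})

test_that("every profile with up to two active flags matches the oracle", {
  mat <- enumerate_profiles(2)
  got <- acmg_combine(tibble::as_tibble(as.data.frame(mat)))
  expect_equal(as.character(got), unname(oracle_classes(mat)))
})

test_that("classify_variants appends a complete, consistent classification", {
  cohort <- generate_cohort(noise_free_config(n_persons = 200, seed = 3))
  pri <- prioritise_variants(cohort$variants)
  cls <- classify_variants(pri)
  expect_true(all(acmg_criteria() %in% names(cls)))
  expect_true(all(!is.na(cls$acmg_class)))
  # subclass is defined exactly for VUS
  expect_equal(cls$vus_subclass == "not_applicable", cls$acmg_class != "vus")
  # planted recipes classify as their target class
  truth <- cohort$truth %>%
    dplyr::filter(mechanism == "variant") %>%
    dplyr::select(person_id, target_class)
  planted <- cls %>% dplyr::inner_join(truth, by = "person_id")
  expect_equal(
    as.character(planted$acmg_class),
    ifelse(planted$target_class == "vus_high", "vus", planted$target_class)
  )
  expect_true(all(planted$vus_subclass[planted$target_class == "vus_high"] == "high"))
})
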