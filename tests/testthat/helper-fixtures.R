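# programmatic fixtures used across test files

make_variant <- function(person_id = "P1", gene = "SOD1", chrom = "21",
                         pos = 1000L, ref = "G", alt = "A",
                         variant_class = "SNV",
                         consequence_terms = "missense_variant",
                         site_quality = 60, genotype_quality = 50,
                         missingness = 0, af_reference = 0, af_internal = 0,
                         zygosity = "heterozygous",
                         insilico_score = NA_real_,
                         clinvar_plp = FALSE,
                         alsod_publications = 0L, alsod_patients = 0L) {
  tibble::tibble(
    person_id = person_id, gene = gene, chrom = chrom, pos = pos, ref = ref,
    alt = alt, variant_class = variant_class,
    consequence_terms = consequence_terms, site_quality = site_quality,
    genotype_quality = genotype_quality, missingness = missingness,
    af_reference = af_reference, af_internal = af_internal,
    zygosity = zygosity, insilico_score = insilico_score,
    clinvar_plp = clinvar_plp, alsod_publications = alsod_publications,
    alsod_patients = alsod_patients
  )
}

make_metrics <- function(n = 5, person_id = sprintf("S%02d", seq_len(n)),
                         titv = 2, n_snv = 21000, n_indel = 1300,
                         n_singleton = 150, inferred_sex = "male",
                         reported_sex = "male", age_onset = 60) {
  tibble::tibble(
    person_id = person_id, titv = titv, n_snv = n_snv, n_indel = n_indel,
    n_singleton = n_singleton, inferred_sex = inferred_sex,
    reported_sex = reported_sex, age_onset = age_onset
  )
}

# a noise-free cohort configuration (planting only, no nuisance features)
noise_free_config <- function(n_persons = 400, seed = 11,
                              panel_probabilities = NULL) {
  cohort_config(
    n_persons = n_persons,
    panel_probabilities = panel_probabilities,
    noise = list(
      background_per_person = 0, sex_mismatch_rate = 0, missing_age_rate = 0
    ),
    seed = seed
  )
}

flat_probs <- function(p) {
  stats::setNames(rep(p, 5), age_group_levels())
}
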