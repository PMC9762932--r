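# synthetic cohort generator with planted, analytically known ground truth

# chromosome assignment for planted coordinates (arbitrary but fixed)
GENE_CHROM <- function(gene) {
  known <- c(
    ALS2 = "2", ANG = "14", ANXA11 = "10", ATXN2 = "12", C21orf2 = "21",
    C9orf72 = "9", CHCHD10 = "22", DAO = "12", DCTN1 = "2", ERBB4 = "2",
    FIG4 = "6", FUS = "16", HNRNPA1 = "12", MATR3 = "5", MOBP = "3",
    NEFH = "22", NEK1 = "4", OPTN = "10", PFN1 = "17", SCFD1 = "14",
    SETX = "9", SIGMAR1 = "9", SOD1 = "21", SPG11 = "15", SQSTM1 = "5",
    TAF15 = "17", TARDBP = "1", TBK1 = "12", TUB4A = "2", UBQLN2 = "X",
    VAPB = "20", VCP = "9"
  )
  out <- unname(known[gene])
  out[is.na(out)] <- "7"
  out
}

# Relative chance that each panel gene supplies a planted sequence variant.
# C9orf72 and ATXN2 are weighted 0: their actionable mechanism here is the
# repeat expansion, governed by repeat_freqs. Per-gene breakdowns of
# actionable results are not published; these weights are a documented,
# arbitrary-but-plausible choice (commonest genes heaviest).
default_gene_weights <- function() {
  w <- stats::setNames(
    rep(0.26 / 18, length(GENOMICS_ENGLAND_PANEL)), GENOMICS_ENGLAND_PANEL
  )
  w[c("SOD1", "TARDBP", "FUS", "TBK1", "OPTN", "SPG11", "FIG4", "ALS2")] <-
    c(0.14, 0.10, 0.10, 0.12, 0.10, 0.08, 0.06, 0.04)
  w[c("C9orf72", "ATXN2")] <- 0
  w / sum(w) # exact normalisation against rounding residue
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated sequencing cohort:
#' demographics, per-age-group probability of carrying at least one
#' clinically actionable finding (for the panel scenario being emulated),
#' which gene or repeat locus supplies the planted finding, and the rates of
#' the realistic nuisance features (background variants, QC-failing sites,
#' sex-mismatched samples, missing onset ages). Defaults emulate a UK-like
#' cohort screened with the Genomics England panel: 1551 persons, 60% male,
#' onset ages from a truncated normal (mean 65, sd 12, truncated to 18-95
#' years), actionable probability 0.23 in the youngest and 0.17 in the oldest
#' onset group (0.222 in between; see [uk_actionable_probabilities()]).
#'
#' @param n_persons Cohort size (positive integer; default 1551).
#' @param sex_ratio Fraction male in `[0, 1]` (default 0.6).
#' @param age_mean,age_sd,age_range Onset-age distribution parameters
#'   (truncated normal; defaults 65, 12, 18-95 years).
#' @param panel_probabilities Named numeric vector, one probability per age
#'   group (names must be exactly [age_group_levels()]).
#' @param gene_weights Named numeric vector over panel genes, summing to 1:
#'   relative probability that each gene supplies a planted sequence variant.
#' @param repeat_freqs Named vector `c(c9orf72 = , atxn2 = )`: share of
#'   planted actionable findings that are a pathogenic C9orf72 expansion or
#'   an intermediate ATXN2 expansion (the rest are sequence variants).
#' @param class_mix Named vector over `pathogenic`, `likely_pathogenic`,
#'   `vus_high`: target ACMG outcome mix of planted sequence variants.
#' @param noise List with `background_per_person` (mean number of benign /
#'   low-VUS / QC-failing background variants per person),
#'   `sex_mismatch_rate` and `missing_age_rate` (per-sample probabilities).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A list of class `als_cohort_config`.
#' @export
cohort_config <- function(n_persons = 1551,
                          sex_ratio = 0.6,
                          age_mean = 65, age_sd = 12, age_range = c(18, 95),
                          panel_probabilities = NULL,
                          gene_weights = default_gene_weights(),
                          repeat_freqs = c(c9orf72 = 0.35, atxn2 = 0.05),
                          class_mix = c(
                            pathogenic = 0.15, likely_pathogenic = 0.25,
                            vus_high = 0.60
                          ),
                          noise = list(
                            background_per_person = 2,
                            sex_mismatch_rate = 0.005,
                            missing_age_rate = 0.01
                          ),
                          seed = 1L) {
  if (is.null(panel_probabilities)) {
    pp <- uk_actionable_probabilities("genomics_england")
    panel_probabilities <- stats::setNames(pp$p, pp$age_group)
  }
  if (length(n_persons) != 1 || !is.finite(n_persons) || n_persons < 1) {
    stop_config("`n_persons` must be a positive integer (an empty cohort is not a cohort).")
  }
  check_prob(sex_ratio, "sex_ratio")
  check_prob(panel_probabilities, "panel_probabilities")
  if (!setequal(names(panel_probabilities), age_group_levels())) {
    stop_config("`panel_probabilities` must name exactly the five age groups.")
  }
  if (any(gene_weights < 0) || abs(sum(gene_weights) - 1) > 1e-8) {
    stop_config("`gene_weights` must be non-negative and sum to 1.")
  }
  check_prob(repeat_freqs, "repeat_freqs")
  if (sum(repeat_freqs) > 1) {
    stop_config("`repeat_freqs` must sum to at most 1.")
  }
  check_prob(
    c(noise$sex_mismatch_rate, noise$missing_age_rate), "noise rates"
  )
  if (noise$background_per_person < 0) {
    stop_config("`background_per_person` must be non-negative.")
  }
  structure(
    list(
      n_persons = as.integer(n_persons), sex_ratio = sex_ratio,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      panel_probabilities = panel_probabilities[age_group_levels()],
      gene_weights = gene_weights, repeat_freqs = repeat_freqs,
      class_mix = class_mix / sum(class_mix), noise = noise,
      seed = as.integer(seed)
    ),
    class = "als_cohort_config"
  )
}

# inverse-CDF draw from a normal truncated to [range[1], range[2]]
rtruncnorm_icdf <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

# planted variant "recipes": annotation patterns whose classification under
# the conservative fixed profile is analytically known
#   pathogenic:        stop_lost in a LOF gene, absent from references
#                      -> PVS1 + PM2 + PM4 -> pathogenic
#   likely_pathogenic: frameshift in a LOF gene, absent from references
#                      -> PVS1 + PM2 -> likely pathogenic
#   vus_high:          missense in a panel gene, absent, mid-range score
#                      -> PM2 only -> VUS, high probability
planted_variant_rows <- function(person_id, sex, gene, target_class,
                                 thresholds = acmg_thresholds()) {
  n <- length(person_id)
  consequence <- unname(c(
    pathogenic = "stop_lost", likely_pathogenic = "frameshift_variant",
    vus_high = "missense_variant"
  )[target_class])
  vclass <- dplyr::if_else(target_class == "likely_pathogenic", "indel", "SNV")
  ref <- dplyr::if_else(vclass == "indel", "AT", "G")
  alt <- rep("A", n)
  zyg <- dplyr::case_when(
    gene == "ALS2" ~ "homozygous",
    gene == "UBQLN2" & sex == "male" ~ "hemizygous",
    TRUE ~ "heterozygous"
  )
  tf <- gene %in% c("TARDBP", "FUS", "SOD1")
  tibble(
    person_id = person_id, gene = gene,
    chrom = GENE_CHROM(gene), pos = sample.int(2e8, n, replace = TRUE),
    ref = unname(ref), alt = alt,
    variant_class = unname(vclass),
    consequence_terms = unname(consequence),
    site_quality = runif(n, 50, 95),
    genotype_quality = sample(30:99, n, replace = TRUE),
    missingness = runif(n, 0, 0.019),
    af_reference = 0, af_internal = 0,
    zygosity = zyg,
    insilico_score = dplyr::if_else(target_class == "vus_high",
      runif(n, 0.3, 0.6), NA_real_
    ),
    clinvar_plp = tf & target_class %in% c("pathogenic", "likely_pathogenic"),
    alsod_publications = dplyr::if_else(tf, sample(1:5, n, replace = TRUE), 0L),
    alsod_patients = dplyr::if_else(tf, sample(2:30, n, replace = TRUE), 0L)
  )
}

# background variants that must be filtered out or classified non-actionable
background_variant_rows <- function(person_id, gene_pool) {
  n <- length(person_id)
  if (n == 0) {
    return(planted_variant_rows(character(), character(), character(), character())[0, ])
  }
  kind <- sample(
    c("common_missense", "rare_synonymous", "vus_low", "qc_fail", "als2_het"),
    n,
    replace = TRUE, prob = c(0.30, 0.25, 0.25, 0.15, 0.05)
  )
  gene <- sample(gene_pool, n, replace = TRUE)
  gene[kind == "als2_het"] <- "ALS2"
  consequence <- dplyr::case_when(
    kind == "rare_synonymous" ~ "synonymous_variant",
    kind == "qc_fail" ~ "stop_gained",
    kind == "als2_het" ~ "frameshift_variant",
    TRUE ~ "missense_variant"
  )
  tibble(
    person_id = person_id, gene = gene,
    chrom = GENE_CHROM(gene), pos = sample.int(2e8, n, replace = TRUE),
    ref = ifelse(kind == "als2_het", "AT", "C"), alt = "T",
    variant_class = ifelse(kind == "als2_het", "indel", "SNV"),
    consequence_terms = consequence,
    site_quality = ifelse(kind == "qc_fail", runif(n, 1, 15), runif(n, 50, 95)),
    genotype_quality = ifelse(kind == "qc_fail",
      sample(0:9, n, replace = TRUE), sample(30:99, n, replace = TRUE)
    ),
    missingness = runif(n, 0, 0.019),
    af_reference = ifelse(kind == "common_missense", runif(n, 0.002, 0.05), 0),
    af_internal = ifelse(kind == "common_missense", runif(n, 0.002, 0.05), 0),
    zygosity = "heterozygous",
    insilico_score = ifelse(kind == "vus_low", runif(n, 0, 0.1), NA_real_),
    clinvar_plp = FALSE,
    alsod_publications = 0L, alsod_patients = 0L
  )
}

#' Generate a synthetic sequencing cohort with planted ground truth
#'
#' Draws persons (sex, onset age), plants actionable findings at the
#' configured per-age-group probabilities — pathogenic C9orf72 expansions,
#' intermediate ATXN2 expansions, or sequence variants whose annotations are
#' built from explicit recipes so that the downstream engine provably
#' classifies them as pathogenic, likely pathogenic or high-probability VUS —
#' and adds background variants and sample-level noise that the pipeline must
#' remove or classify as non-actionable. Ground-truth labels are emitted in a
#' sidecar table (`truth`), never in the variant table.
#'
#' @param config A [cohort_config()].
#' @return A list of class `als_cohort` with tibbles `persons`, `variants`,
#'   `repeat_calls`, `sample_metrics`, `truth`, and the `config`.
#'   Deterministic given the config (including its seed).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "als_cohort_config")) {
    stop_config("`config` must be created by cohort_config().")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_persons
  person_id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  age <- rtruncnorm_icdf(n, config$age_mean, config$age_sd, config$age_range)
  age_group <- as.character(bin_age(age))
  p_act <- unname(config$panel_probabilities[age_group])
  actionable <- runif(n) < p_act

  rf <- config$repeat_freqs
  mech <- rep("none", n)
  mech[actionable] <- sample(
    c("repeat_C9orf72", "repeat_ATXN2", "variant"),
    sum(actionable),
    replace = TRUE,
    prob = c(rf[["c9orf72"]], rf[["atxn2"]], 1 - sum(rf))
  )

  # planted sequence variants
  is_var <- mech == "variant"
  target_class <- rep(NA_character_, n)
  planted_gene <- rep(NA_character_, n)
  if (any(is_var)) {
    target_class[is_var] <- sample(
      names(config$class_mix), sum(is_var),
      replace = TRUE, prob = config$class_mix
    )
    lof <- intersect(acmg_thresholds()$lof_genes, names(config$gene_weights))
    lof_w <- config$gene_weights[lof] / sum(config$gene_weights[lof])
    need_lof <- is_var &
      target_class %in% c("pathogenic", "likely_pathogenic")
    planted_gene[need_lof] <- sample(
      lof, sum(need_lof),
      replace = TRUE, prob = lof_w
    )
    need_any <- is_var & target_class == "vus_high"
    planted_gene[need_any] <- sample(
      names(config$gene_weights), sum(need_any),
      replace = TRUE, prob = config$gene_weights
    )
  }
  planted <- planted_variant_rows(
    person_id[is_var], sex[is_var], planted_gene[is_var], target_class[is_var]
  )

  # background variants
  n_bg <- rpois(n, config$noise$background_per_person)
  bg_person <- rep(person_id, n_bg)
  gene_pool <- c(names(config$gene_weights), "KIF5A", "DPP6", "UNC13A")
  background <- background_variant_rows(bg_person, gene_pool)
  variants <- bind_rows(planted, background) %>%
    arrange(.data$person_id, .data$gene, .data$pos)

  # repeat calls: both loci for everyone
  c9 <- ifelse(mech == "repeat_C9orf72",
    sample(45:900, n, replace = TRUE),
    sample(2:10, n, replace = TRUE)
  )
  atxn2 <- ifelse(mech == "repeat_ATXN2",
    sample(29:33, n, replace = TRUE),
    sample(18:26, n, replace = TRUE)
  )
  repeat_calls <- bind_rows(
    tibble(person_id = person_id, gene = "C9orf72", repeat_count = c9),
    tibble(person_id = person_id, gene = "ATXN2", repeat_count = atxn2)
  ) %>% arrange(.data$person_id, .data$gene)

  # sample metrics with configured QC failure modes
  mismatch <- runif(n) < config$noise$sex_mismatch_rate
  no_age <- runif(n) < config$noise$missing_age_rate
  reported_sex <- ifelse(mismatch,
    ifelse(sex == "male", "female", "male"), sex
  )
  sample_metrics <- tibble(
    person_id = person_id,
    titv = rnorm(n, 2.0, 0.05),
    n_snv = round(rnorm(n, 21000, 300)),
    n_indel = round(rnorm(n, 1300, 60)),
    n_singleton = round(rnorm(n, 150, 15)),
    inferred_sex = sex,
    reported_sex = reported_sex,
    age_onset = ifelse(no_age, NA_real_, age)
  )

  persons <- tibble(
    person_id = person_id, sex = reported_sex,
    age_onset = ifelse(no_age, NA_real_, age)
  )
  truth <- tibble(
    person_id = person_id, actionable = actionable, mechanism = mech,
    gene = ifelse(mech == "variant", planted_gene,
      ifelse(mech == "none", NA_character_, sub("repeat_", "", mech))
    ),
    target_class = target_class,
    true_sex = sex, true_age_onset = age, age_group = age_group
  )

  structure(
    list(
      persons = persons, variants = variants, repeat_calls = repeat_calls,
      sample_metrics = sample_metrics, truth = truth, config = config
    ),
    class = "als_cohort"
  )
}

#' Configuration for the synthetic incidence register
#'
#' @param strata Data frame with columns `age_group`, `sex`, `population`
#'   (persons at risk in the catchment) and `rate` (true incidence per
#'   100,000 person-years). Defaults to a UK-like register: the published
#'   age/sex rates with catchment populations scaled from the back-calculated
#'   standard populations to a 12.5-million catchment.
#' @param years Observation duration in years (default 2; `0` is allowed and
#'   yields zero person-years and zero cases).
#' @param familial_fraction_range Plausible range of the familial fraction
#'   (default 0.05-0.20; recorded for documentation — the policy model uses
#'   its midpoint through the 0.875 sporadic factor).
#' @param seed Integer seed.
#' @return A list of class `als_register_config`.
#' @export
register_config <- function(strata = NULL, years = 2,
                            familial_fraction_range = c(0.05, 0.20),
                            seed = 1L) {
  if (is.null(strata)) {
    std <- uk_standard_population() %>%
      inner_join(uk_als_incidence(), by = c("age_group", "sex"))
    strata <- std %>%
      transmute(
        .data$age_group, .data$sex,
        population = .data$standard_pop * 12.5e6 / sum(.data$standard_pop),
        rate = .data$rate
      )
  }
  check_columns(strata, c("age_group", "sex", "population", "rate"), "strata")
  if (any(strata$population < 0)) stop_config("Populations must be >= 0.")
  if (any(strata$rate < 0)) stop_config("Rates must be >= 0.")
  if (years < 0) stop_config("`years` must be >= 0.")
  check_prob(familial_fraction_range, "familial_fraction_range")
  structure(
    list(
      strata = as_tibble(strata), years = years,
      familial_fraction_range = familial_fraction_range,
      seed = as.integer(seed)
    ),
    class = "als_register_config"
  )
}

#' Generate a synthetic incidence register
#'
#' Person-years per stratum are `population * years`; case counts are drawn
#' from a Poisson law with mean `rate * person_years / 1e5`. Deterministic
#' given the config.
#'
#' @param config A [register_config()].
#' @return Tibble with columns `age_group`, `sex`, `population`,
#'   `person_years`, `cases` (and the true `rate` used, for reference).
#' @export
generate_register <- function(config = register_config()) {
  if (!inherits(config, "als_register_config")) {
    stop_config("`config` must be created by register_config().")
  }
  with_seed(config$seed, {
    config$strata %>%
      mutate(
        person_years = .data$population * config$years,
        cases = rpois(
          dplyr::n(), .data$rate * .data$person_years / 1e5
        )
      )
  })
}
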