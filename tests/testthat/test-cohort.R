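test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_persons = 0), class = "alsyield_config_error")
  expect_error(
    cohort_config(panel_probabilities = flat_probs(1.2)),
    class = "alsyield_config_error"
  )
  expect_error(
    cohort_config(panel_probabilities = c(a = 0.1)),
    class = "alsyield_config_error"
  )
  expect_error(
    cohort_config(gene_weights = c(SOD1 = 0.4, FUS = 0.4)),
    class = "alsyield_config_error"
  )
  expect_error(
    register_config(strata = tibble::tibble(
      age_group = "<40", sex = "male", population = 1000, rate = -1
    )),
    class = "alsyield_config_error"
  )
})

test_that("the generator is byte-deterministic given its config", {
  cfg <- cohort_config(n_persons = 120, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$variants, b$variants)
  expect_identical(a$repeat_calls, b$repeat_calls)
  expect_identical(a$sample_metrics, b$sample_metrics)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_persons = 120, seed = 43))
  expect_false(identical(a$persons, c$persons))
})

test_that("an all-zero configuration yields zero actionable persons end to end", {
  cohort <- generate_cohort(noise_free_config(
    n_persons = 150, seed = 2, panel_probabilities = flat_probs(0)
  ))
  expect_equal(nrow(cohort$variants), 0)
  report <- run_pipeline(cohort)
  expect_false(any(report$actionability$actionable))
  expect_equal(sum(report$yield$k), 0)
})

test_that("planted actionable fraction matches the configured probability (binomial oracle)", {
  # flat probability 0.2; the mean realised fraction over many seeds must sit
  # within 3 binomial standard errors of the target
  n <- 1000
  seeds <- 1:200
  fractions <- vapply(seeds, function(s) {
    cohort <- generate_cohort(cohort_config(
      n_persons = n, panel_probabilities = flat_probs(0.2), seed = s
    ))
    mean(cohort$truth$actionable)
  }, numeric(1))
  se_mean <- sqrt(0.2 * 0.8 / (n * length(seeds)))
  expect_lt(abs(mean(fractions) - 0.2), 3 * se_mean)
})

test_that("marginal age, sex and carrier distributions match the config", {
  # chi-square goodness of fit at alpha = 0.01 should pass for almost all seeds
  n <- 2000
  seeds <- 1:40
  cfg0 <- cohort_config(n_persons = n, seed = 1)
  lo <- pnorm(cfg0$age_range[1], cfg0$age_mean, cfg0$age_sd)
  hi <- pnorm(cfg0$age_range[2], cfg0$age_mean, cfg0$age_sd)
  cuts <- c(18, 40, 50, 60, 70, 95)
  p_age <- diff(pnorm(cuts, cfg0$age_mean, cfg0$age_sd)) / (hi - lo)
  pass <- vapply(seeds, function(s) {
    cohort <- generate_cohort(cohort_config(n_persons = n, seed = s))
    truth <- cohort$truth
    obs_age <- table(cut(truth$true_age_onset, cuts, right = FALSE))
    ok_age <- stats::chisq.test(obs_age, p = p_age)$p.value > 0.01
    ok_sex <- stats::binom.test(
      sum(truth$true_sex == "male"), n, 0.6
    )$p.value > 0.01
    exp_p <- mean(cfg0$panel_probabilities[truth$age_group])
    ok_carrier <- abs(mean(truth$actionable) - exp_p) <
      4 * sqrt(exp_p * (1 - exp_p) / n)
    ok_age && ok_sex && ok_carrier
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("planted ground truth and pipeline output agree perfectly at noise zero", {
  cohort <- generate_cohort(noise_free_config(n_persons = 700, seed = 31))
  report <- run_pipeline(cohort)
  ge <- report$actionability %>%
    dplyr::filter(panel == "genomics_england") %>%
    dplyr::arrange(person_id)
  truth <- dplyr::arrange(cohort$truth, person_id)
  expect_equal(ge$person_id, truth$person_id)
  expect_equal(ge$actionable, truth$actionable)
})

test_that("register cases follow the configured Poisson law", {
  strata <- tibble::tibble(
    age_group = "50-59", sex = "male", population = 5e5, rate = 2
  )
  cases <- vapply(1:1000, function(s) {
    generate_register(register_config(strata = strata, years = 2, seed = s))$cases
  }, numeric(1))
  # mean 2 * 1e6 / 1e5 = 20; 3 SE band for the Monte-Carlo mean
  expect_lt(abs(mean(cases) - 20), 3 * sqrt(20 / 1000))

  zero_rate <- generate_register(register_config(
    strata = dplyr::mutate(strata, rate = 0), seed = 1
  ))
  expect_equal(zero_rate$cases, 0)

  no_years <- generate_register(register_config(
    strata = strata, years = 0, seed = 1
  ))
  expect_equal(no_years$person_years, 0)
  expect_equal(no_years$cases, 0)

  reg <- generate_register(register_config(seed = 4))
  expect_equal(reg$person_years, reg$population * 2)
  expect_identical(reg, generate_register(register_config(seed = 4)))
})
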