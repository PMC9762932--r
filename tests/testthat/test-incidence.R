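test_that("crude rates and expected counts follow the definitions", {
  expect_equal(crude_rate(0, 1e6), 0)
  expect_equal(crude_rate(10, 5e5), 2)
  expect_equal(crude_rate(20, 1e6), 2) # scale invariance
  expect_error(crude_rate(1, 0), class = "alsyield_input_error")
  expect_equal(expected_count(2, 1e5), 2)
  expect_equal(expected_count(0, 123456), 0)
})

test_that("sporadic adjustment is the configured linear scaling", {
  expect_equal(sporadic_adjust(100), 87.5)
  expect_equal(sporadic_adjust(0), 0)
  a <- runif(5, 0, 50)
  b <- runif(5, 0, 50)
  expect_equal(sporadic_adjust(a) + sporadic_adjust(b), sporadic_adjust(a + b))
})

test_that("single-stratum gamma interval equals the Poisson exact interval", {
  # independent closed form: Garwood interval via chi-square quantiles
  d <- 100
  garwood <- c(qchisq(0.025, 2 * d) / 2, qchisq(0.975, 2 * d + 2) / 2)
  g <- gamma_ci(d, 1)
  expect_equal(g$lower, garwood[1], tolerance = 0.01)
  expect_equal(g$upper, garwood[2], tolerance = 0.01)

  # zero counts: lower bound 0, positive upper bound
  g0 <- gamma_ci(c(0, 0), c(1, 2))
  expect_equal(g0$lower, 0)
  expect_gt(g0$upper, 0)
  expect_error(gamma_ci(numeric()), class = "alsyield_input_error")
})

test_that("standardizing to the study population reproduces the crude rate", {
  reg <- tibble::tibble(
    age_group = rep(age_group_levels(), 2),
    sex = rep(c("male", "female"), each = 5),
    cases = c(3, 10, 25, 40, 45, 2, 6, 12, 38, 50),
    person_years = c(2, 1.8, 1.5, 1.2, 1, 2.1, 1.9, 1.6, 1.3, 1.1) * 1e6,
    standard_pop = NA_real_
  )
  reg$standard_pop <- reg$person_years # self-standard
  std <- standardized_rate(reg)
  crude <- crude_rate(sum(reg$cases), sum(reg$person_years))
  expect_equal(std$point, crude, tolerance = 1e-12)
})

test_that("the missed-results estimator handles cutoffs and degenerate inputs", {
  expected <- uk_als_incidence() %>%
    dplyr::group_by(age_group) %>%
    dplyr::summarise(expected = sum(expected), .groups = "drop")

  # probabilities all zero above the cutoff: nothing missed
  probs0 <- tibble::tibble(
    age_group = age_group_levels(), p = c(0.5, 0, 0, 0, 0)
  )
  m0 <- missed_estimate(expected, probs0)
  expect_equal(m0$missed, 0)
  expect_gt(m0$total, 0)

  # cutoff below every group: everything missed
  m_all <- missed_estimate(
    expected, uk_actionable_probabilities(),
    policy_config(age_cutoff = 0)
  )
  expect_equal(m_all$proportion, 1)

  # raising the cutoff never increases the missed count
  missed_by_cutoff <- vapply(
    c(0, 40, 50, 60, 70),
    function(cut) {
      missed_estimate(
        expected, uk_actionable_probabilities(),
        policy_config(age_cutoff = cut)
      )$missed
    },
    numeric(1)
  )
  expect_true(all(diff(missed_by_cutoff) <= 0))

  expect_error(
    missed_estimate(expected, dplyr::mutate(probs0, p = p + 2)),
    class = "alsyield_config_error"
  )
  expect_error(
    missed_estimate(expected[1:2, ], probs0[1:3, ]) |> invisible(),
    NA
  ) # subset of groups with probabilities present is fine
  expect_error(
    missed_estimate(expected, probs0[2:5, ]),
    class = "alsyield_input_error"
  ) # a group without a probability is not
})

test_that("published expected diagnoses and calibrated probabilities reproduce the annual missed counts", {
  expected <- uk_als_incidence() %>%
    dplyr::select(age_group, sex, expected)
  ge <- missed_estimate(expected, uk_actionable_probabilities("genomics_england"))
  # +/- 1 person-per-year tolerance for rounding ambiguity in the source
  expect_lte(abs(round(ge$missed) - 115), 1)
  expect_lte(abs(round(ge$total) - 117), 1)
  expect_equal(round(unname(ge$ci), 2), c(0.96, 1.01))
  expect_equal(round(100 * ge$proportion), 98)

  fg <- missed_estimate(expected, uk_actionable_probabilities("four_gene"))
  expect_lte(abs(round(fg$missed) - 56), 1)
  expect_lte(abs(round(fg$total) - 58), 1)
  expect_gte(fg$proportion, 0.95) # printed 0.97; counts carry a +/-1 slack

  # per-sex contributions sum to the totals
  expect_equal(sum(ge$by_sex$missed), ge$missed)
  expect_equal(sum(ge$by_sex$total), ge$total)
})

test_that("incidence_table matches hand arithmetic on a tiny register", {
  reg <- tibble::tibble(
    age_group = "60-69", sex = "male", cases = 20,
    person_years = 1e6, standard_pop = 2e6
  )
  tab <- incidence_table(reg)
  expect_equal(tab$rate, 2)
  expect_equal(tab$expected, 2 * 2e6 / 1e5 * 0.875)
  # rate interval is the Garwood interval scaled per 100,000
  expect_equal(tab$rate_lower, qchisq(0.025, 40) / 2 * 1e5 / 1e6,
    tolerance = 1e-10
  )
  # expected interval = rate interval scaled by sporadic_factor * std/1e5
  expect_equal(
    tab$expected_lower / tab$rate_lower,
    0.875 * 2e6 / 1e5,
    tolerance = 1e-10
  )
})
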