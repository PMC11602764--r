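test_that("clean cohorts reproduce the model's category frequencies", {
  sim <- clean_sim(5000, n_items = 4, K = 5, seed = 21, bank_seed = 22)
  vals <- unclass(as.matrix(sim$responses))
  expect_false(anyNA(vals))
  theta <- sim$cohort$true_theta
  for (j in 1:4) {
    emp <- tabulate(vals[, j] + 1L, 5) / nrow(vals)
    expected <- colMeans(category_probabilities(sim$true_bank[[j]], theta))
    se <- sqrt(expected * (1 - expected) / nrow(vals))
    expect_true(all(abs(emp - expected) <= 3 * se + 1e-9))
  }
})

test_that("degenerate skip rates yield an all-missing matrix", {
  cc <- cohort_config(n_respondents = 50,
                      scales = list(list(name = "s", n_items = 3,
                                         n_categories = 4)),
                      skip_rate_normal = 1, skip_rate_impaired = 1,
                      seed = 1)
  sim <- simulate_cohort(cc)
  expect_true(all(is.na(unclass(as.matrix(sim$responses)))))
})

test_that("impairment prevalence matches the configured rate", {
  cc <- cohort_config(n_respondents = 10000, prevalence = 0.18, seed = 31)
  sim <- simulate_cohort(cc)
  # binomial 99% interval around 0.18 at n = 10000
  half <- qnorm(0.995) * sqrt(0.18 * 0.82 / 10000)
  expect_lt(abs(mean(sim$cohort$impairment) - 0.18), half)
})

test_that("cohorts are bit-identical under the same seed", {
  cc <- cohort_config(n_respondents = 300, seed = 99)
  s1 <- simulate_cohort(cc)
  s2 <- simulate_cohort(cc)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$cohort, s2$cohort)
  s3 <- simulate_cohort(cohort_config(n_respondents = 300, seed = 100))
  expect_false(identical(unclass(s1$responses), unclass(s3$responses)))
})

test_that("default cohorts show the intended missingness and structure", {
  cc <- cohort_config(n_respondents = 2000, seed = 5)
  sim <- simulate_cohort(cc)
  expect_equal(ncol(sim$responses), 25)  # 6 + 7 + 7 + 5 items
  miss <- mean(is.na(unclass(as.matrix(sim$responses))))
  expect_true(miss > 0.005 && miss < 0.04)
  expect_setequal(unique(itemScales(sim$responses)),
                  c("optimism", "hopelessness", "purpose",
                    "life_satisfaction"))
  expect_true(all(sim$cohort$age >= 50))
  # age-impairment association: oldest bin clearly exceeds youngest
  ci_by_bin <- tapply(sim$cohort$impairment,
                      lqrscreen:::.age_bin(sim$cohort$age), mean)
  expect_gt(ci_by_bin[["80+"]], ci_by_bin[["50-59"]] + 0.1)
})

test_that("straight-lined careless rows have lower response variance", {
  cc <- cohort_config(n_respondents = 1500,
                      careless_rate_normal = 0.9,
                      careless_rate_impaired = 0.9,
                      straightline_fraction = 1, reverse_keyed = FALSE,
                      skip_rate_normal = 0, skip_rate_impaired = 0,
                      seed = 41)
  straight <- simulate_cohort(cc)
  clean <- clean_sim(1500, n_items = 25, K = 6, seed = 41)
  rowvar <- function(sim) mean(apply(unclass(as.matrix(sim$responses)),
                                     1, var))
  expect_lt(rowvar(straight), rowvar(clean))
})

test_that("with no injected differences the groups are exchangeable", {
  # two-sample tests on mean responses should reject at about the nominal
  # alpha = 0.01 rate
  pvals <- vapply(1:20, function(s) {
    sim <- clean_sim(400, n_items = 6, K = 6, seed = 300 + s)
    m <- rowMeans(unclass(as.matrix(sim$responses)))
    stats::t.test(m ~ sim$cohort$impairment)$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 3)
})

test_that("cognition scores are consistent with the impairment label", {
  cc <- cohort_config(n_respondents = 500, seed = 51)
  sim <- simulate_cohort(cc)
  cohort <- assign_cognition_scores(sim$cohort, seed = 52)
  expect_true(all(cohort$cognition_score >= 0 &
                    cohort$cognition_score <= 27))
  expect_true(all(cohort$cognition_score[cohort$impairment == 1] <= 11))
  expect_true(all(cohort$cognition_score[cohort$impairment == 0] >= 12))
  lab <- derive_ci_label(cohort$cognition_score)
  expect_identical(as.integer(lab$binary_ci), cohort$impairment)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_respondents = 1), "n_respondents")
  expect_error(cohort_config(prevalence = 0), "prevalence")
  expect_error(cohort_config(careless_rate_normal = 1.2), "rates")
  expect_error(cohort_config(straightline_fraction = -0.1), "rates")
})
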