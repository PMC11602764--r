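test_that("AUC equals pair counting, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rbinom(10, 1, 0.5) + c(1, rep(0, 9)) * 0),
               0.5)
  withr::with_seed(71, {
    for (rep in 1:10) {
      y <- rbinom(200, 1, 0.3)
      if (length(unique(y)) < 2) next
      s <- round(runif(200), 2)  # ties on purpose
      expect_equal(auc(s, y), auc_bruteforce(s, y), tolerance = 1e-12)
    }
  })
  expect_error(auc(runif(5), rep(0, 5)), "single class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(72, {
    y <- rbinom(300, 1, 0.4)
    s <- plogis(rnorm(300) + 0.8 * y)
  })
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(73, {
    y <- rbinom(150, 1, 0.3)
    s <- runif(150)
  })
  base <- auc(s, y)
  expect_equal(auc(plogis(5 * s - 2), y), base, tolerance = 1e-12)
  expect_equal(auc(s^3, y), base, tolerance = 1e-12)
})

test_that("efficiency curves have the right endpoints and geometry", {
  withr::with_seed(74, {
    y <- rbinom(300, 1, 0.25)
    s <- plogis(rnorm(300) + y)
  })
  curve <- efficiency_curve(s, y)
  expect_true(all(curve$proportion_referred >= 0 &
                    curve$proportion_referred <= 1))
  expect_true(all(diff(curve$proportion_referred) <= 0))
  expect_true(all(diff(curve$proportion_identified) <= 0))
  expect_equal(curve$proportion_referred[1], 1)      # threshold 0
  expect_equal(curve$proportion_identified[1], 1)
  n <- nrow(curve)
  expect_equal(curve$proportion_referred[n], 0)      # threshold 1
  expect_equal(curve$proportion_identified[n], 0)
  # informative scores put the curve weakly left of the diagonal on
  # average exactly when AUC > 0.5
  gap <- mean(curve$proportion_identified - curve$proportion_referred)
  expect_gt(auc(s, y), 0.5)
  expect_gt(gap, 0)
})

test_that("the curve reproduces the selected decision exactly", {
  withr::with_seed(75, {
    y <- rbinom(400, 1, 0.2)
    s <- plogis(rnorm(400) + 1.2 * y)
  })
  d <- select_threshold(s, y, 4)
  curve <- efficiency_curve(s, y)
  row <- curve[curve$threshold == d$threshold, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$proportion_referred * length(y), d$n_referred)
  expect_equal(row$proportion_identified * sum(y), d$n_cases_identified)
})

test_that("rule points behave like indicator-score efficiency points", {
  cc <- cohort_config(n_respondents = 3000, seed = 76)
  cohort <- simulate_cohort(cc)$cohort
  for (r in c("age65", "high_blood_pressure", "stroke")) {
    pt <- rule_point(cohort, r)
    ind <- as.numeric(rule_strategy(r)$predicate(cohort))
    curve <- efficiency_curve(ind, cohort$impairment)
    at_half <- curve[curve$threshold == 0.5, ]
    expect_equal(pt[["proportion_referred"]], at_half$proportion_referred)
    expect_equal(pt[["proportion_identified"]],
                 at_half$proportion_identified)
  }
  # degenerate rules
  none <- rule_strategy("none", function(d) rep(FALSE, nrow(d)))
  expect_equal(unname(rule_point(cohort, none)), c(0, 0))
  all_ <- rule_strategy("all", function(d) rep(TRUE, nrow(d)))
  expect_equal(unname(rule_point(cohort, all_)), c(1, 1))
  expect_error(rule_point(cohort[, c("respondent_id", "impairment")],
                          "age65"), "age")
})

test_that("age-independent rules sit on the diagonal", {
  cc <- cohort_config(n_respondents = 6000,
                      age_impairment_association = FALSE, seed = 77)
  cohort <- simulate_cohort(cc)$cohort
  pt <- rule_point(cohort, "age65")
  n1 <- sum(cohort$impairment)
  se <- sqrt(pt[["proportion_referred"]] *
               (1 - pt[["proportion_referred"]]) / n1)
  expect_lt(abs(pt[["proportion_identified"]] -
                  pt[["proportion_referred"]]), 3 * se)
})

test_that("stratified reports conserve counts and flag degenerate bins", {
  cc <- cohort_config(n_respondents = 2500, seed = 78)
  sim <- simulate_cohort(cc)
  y <- sim$cohort$impairment
  withr::with_seed(79, s <- plogis(rnorm(2500) + 0.8 * y))
  rep_ <- stratified_report(s, y, sim$cohort, cost_ratio = 4)
  expect_equal(sum(rep_$by_age_group$n), rep_$overall$n)
  expect_equal(sum(rep_$by_age_group$n_impaired), rep_$overall$n_impaired)
  expect_equal(sum(rep_$by_age_group$n_referred), rep_$overall$n_referred)
  expect_equal(sum(rep_$by_age_group$n_identified),
               rep_$overall$n_identified)
  # a cohort entirely inside one bin populates only that bin
  young <- sim$cohort$age < 60
  rep_y <- stratified_report(s[young], y[young],
                             sim$cohort[young, ], cost_ratio = 4)
  expect_equal(rep_y$by_age_group$n[1], sum(young))
  expect_true(all(rep_y$by_age_group$n[-1] == 0))
  expect_true(all(is.na(rep_y$by_age_group$auc[-1])))
})
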