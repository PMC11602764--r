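test_that("cognition-score bands partition 0-27 exactly", {
  lab <- derive_ci_label(0:27)
  expect_identical(as.character(lab$category),
                   c(rep("dementia", 7), rep("cind", 5), rep("normal", 16)))
  expect_identical(lab$binary_ci, lab$category != "normal")
  expect_identical(lab$binary_ci, 0:27 <= 11)
  # the spot values: 5 -> dementia, 9 -> cind, 15 -> normal
  expect_identical(as.character(derive_ci_label(c(5, 9, 15))$category),
                   c("dementia", "cind", "normal"))
  expect_error(derive_ci_label(28), "0, 27")
  expect_error(derive_ci_label(-1), "0, 27")
  expect_error(derive_ci_label(3.5), "integers")
})

test_that("imputation is an identity on complete tables", {
  df <- data.frame(a = 1:5, b = c(2, 4, 6, 8, 10))
  expect_identical(iterative_impute(df), df)
})

test_that("imputation completes tables without touching observed cells", {
  sim <- clean_sim(400, seed = 101)
  vals <- unclass(as.matrix(sim$responses))
  withr::with_seed(102, {
    mask <- matrix(runif(length(vals)) < 0.05, nrow(vals))
  })
  holed <- vals; holed[mask] <- NA_integer_
  rm_ <- response_matrix(holed, itemCategories(sim$responses))
  filled <- iterative_impute(rm_)
  fv <- unclass(as.matrix(filled))
  expect_false(anyNA(fv))
  expect_identical(fv[!mask], vals[!mask])
  k <- itemCategories(rm_)
  for (j in seq_len(ncol(fv)))
    expect_true(all(fv[, j] >= 0 & fv[, j] <= k[j] - 1))
})

test_that("regression imputation beats marginal-mode imputation", {
  err_reg <- err_mode <- numeric(10)
  for (s in 1:10) {
    sim <- clean_sim(400, seed = 110 + s)
    vals <- unclass(as.matrix(sim$responses))
    mask <- withr::with_seed(130 + s,
      matrix(runif(length(vals)) < 0.05, nrow(vals)))
    holed <- vals; holed[mask] <- NA_integer_
    rm_ <- response_matrix(holed, itemCategories(sim$responses))
    filled <- unclass(as.matrix(iterative_impute(rm_)))
    err_reg[s] <- mean(abs(filled[mask] - vals[mask]))
    modes <- apply(holed, 2, function(v) {
      tt <- table(v)
      as.integer(names(tt)[which.max(tt)])
    })
    mode_fill <- matrix(modes, nrow(vals), ncol(vals), byrow = TRUE)
    err_mode[s] <- mean(abs(mode_fill[mask] - vals[mask]))
  }
  expect_lte(mean(err_reg), mean(err_mode))
})

test_that("entirely missing columns are reported by name", {
  df <- data.frame(ok = c(1, 2, NA, 4), gone = rep(NA_real_, 4))
  expect_error(iterative_impute(df), "gone")
})

test_that("stratified splits match prevalence and are deterministic", {
  cc <- cohort_config(n_respondents = 10000, prevalence = 0.18, seed = 7)
  sim <- simulate_cohort(cc)
  sp <- stratified_split(sim$cohort, split_spec(0.3, seed = 8))
  man <- sp$manifest
  # partitions are disjoint and exhaustive
  expect_setequal(c(sp$train, sp$test), sim$cohort$respondent_id)
  expect_length(intersect(sp$train, sp$test), 0)
  prev <- tapply(sim$cohort$impairment,
                 man$partition[match(sim$cohort$respondent_id,
                                     man$respondent_id)], mean)
  expect_lt(abs(prev[["test"]] - prev[["train"]]), 0.005)
  sp2 <- stratified_split(sim$cohort, split_spec(0.3, seed = 8))
  expect_identical(sp, sp2)
  sp3 <- stratified_split(sim$cohort, split_spec(0.3, seed = 9))
  expect_false(identical(sp$test, sp3$test))
})

test_that("tiny splits allocate positives exactly", {
  cohort <- data.frame(respondent_id = c("a", "b", "c", "d"),
                       impairment = c(1L, 1L, 0L, 0L))
  sp <- stratified_split(cohort, split_spec(0.5, seed = 1))
  man <- sp$manifest
  for (p in c("train", "test"))
    expect_equal(sum(cohort$impairment[man$partition == p]), 1L)
})

test_that("sub-minimal strata fall back to training with a warning", {
  cohort <- data.frame(respondent_id = c("a", "b", "c"),
                       impairment = c(1L, 0L, 0L))
  expect_warning(sp <- stratified_split(cohort, split_spec(0.4, seed = 1)),
                 "fewer than 2")
  expect_true("a" %in% sp$train)
})
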