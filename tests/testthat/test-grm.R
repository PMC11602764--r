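test_that("category probabilities match closed-form logistic values", {
  # dichotomous item at its threshold
  expect_equal(category_probabilities(grm_item("d", 1, 0), 0),
               c(`0` = 0.5, `1` = 0.5), tolerance = 1e-12)
  # symmetric 3-category item: 1 - plogis(1.5) each tail at theta = 0
  p <- category_probabilities(symmetric_item(), 0)
  tail <- 1 - stats::plogis(1.5)
  expect_equal(unname(p), c(tail, 1 - 2 * tail, tail), tolerance = 1e-12)
  expect_equal(unname(round(p, 5)), c(0.18243, 0.63515, 0.18243))
})

test_that("probabilities normalise and concentrate in the limits", {
  bank <- generate_item_bank(8, 5, seed = 2)
  thetas <- seq(-5, 5, length.out = 21)
  for (it in bank) {
    p <- category_probabilities(it, thetas)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, length(thetas)), tolerance = 1e-12)
  }
  it <- bank[[1]]
  expect_gt(category_probabilities(it, 50)[it$n_categories], 1 - 1e-10)
  expect_gt(category_probabilities(it, -50)[1], 1 - 1e-10)
})

test_that("cumulative boundary curves are monotone in category and theta", {
  bank <- generate_item_bank(5, 6, seed = 3)
  thetas <- seq(-4, 4, length.out = 41)
  for (it in bank) {
    p <- category_probabilities(it, thetas)
    # P*(X >= k) via reverse cumulative sums
    pstar <- t(apply(p, 1, function(row) rev(cumsum(rev(row)))))[, -1]
    expect_true(all(diff(t(pstar)) < 0))        # decreasing in k
    expect_true(all(apply(pstar, 2, diff) > 0)) # increasing in theta
  }
})

test_that("expected response is increasing with the correct limits", {
  expect_equal(expected_response(symmetric_item(), 0), 1, tolerance = 1e-12)
  bank <- generate_item_bank(4, 6, seed = 4)
  grid <- seq(-4, 4, length.out = 100)
  for (it in bank) {
    e <- expected_response(it, grid)
    expect_true(all(diff(e) > 0))
    expect_true(all(e >= 0 & e <= it$n_categories - 1))
  }
  it <- bank[[1]]
  expect_equal(expected_response(it, -40), 0, tolerance = 1e-8)
  expect_equal(expected_response(it, 40), it$n_categories - 1,
               tolerance = 1e-8)
})

test_that("M-step gradient matches finite differences", {
  set.seed(5)
  nodes <- seq(-4, 4, length.out = 21)
  r <- matrix(runif(6 * 21), 6, 21)
  z <- c(log(1.3), -0.8, log(c(0.5, 0.7, 0.4, 0.9)))
  g <- lqrscreen:::.item_grad(z, r, nodes)
  for (i in seq_along(z)) {
    e <- replace(rep(0, length(z)), i, 1e-6)
    num <- (lqrscreen:::.item_obj(z + e, r, nodes) -
              lqrscreen:::.item_obj(z - e, r, nodes)) / 2e-6
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("EM increases the marginal log-likelihood and recovers parameters", {
  sim <- clean_sim(1500, seed = 5)
  fit <- fit_grm(sim$responses)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_true(fit$converged)
  expect_lt(sqrt(mean((bank_discriminations(fit$bank) -
                         bank_discriminations(sim$true_bank))^2)), 0.15)
  expect_lt(sqrt(mean((bank_thresholds(fit$bank) -
                         bank_thresholds(sim$true_bank))^2)), 0.15)
  # maximum-likelihood dominance over the generating parameters
  expect_gte(fit$loglik,
             marginal_loglik(sim$responses, sim$true_bank))
})

test_that("degenerate items are rejected with the item named", {
  sim <- clean_sim(200, seed = 6)
  vals <- unclass(as.matrix(sim$responses))
  vals[, 3] <- 0L
  rm_ <- response_matrix(vals, itemCategories(sim$responses))
  expect_error(fit_grm(rm_), "q03")
  expect_error(fit_grm(response_matrix(matrix(NA_integer_, 4, 2), 3)),
               "missing")
})

test_that("fitted trait scale is anchored by the prior", {
  sim <- clean_sim(3000, seed = 7)
  fit <- fit_grm(sim$responses)
  th <- estimate_theta_eap(sim$responses, fit$bank)
  expect_lt(abs(mean(th$theta)), 0.1)
  expect_true(sd(th$theta) > 0.85 && sd(th$theta) < 1.15)
  expect_true(all(th$posterior_sd <= 1 + 1e-8))
})

test_that("EAP agrees with a dense-grid posterior oracle", {
  bank <- generate_item_bank(6, 6, seed = 8)
  for (s in 1:10) {
    row <- draw_row(bank, rnorm(1), seed = s)
    est <- estimate_theta_eap(row, bank,
                              quadrature_config(4001, bounds = c(-8, 8)))
    oracle <- eap_bruteforce(row, bank)
    expect_equal(est$theta, unname(oracle["theta"]), tolerance = 1e-6)
    expect_equal(est$posterior_sd, unname(oracle["sd"]), tolerance = 1e-6)
  }
})

test_that("an all-missing row returns the prior", {
  bank <- generate_item_bank(4, 5, seed = 9)
  est <- estimate_theta_eap(rep(NA_integer_, 4), bank)
  expect_identical(est$theta, 0)
  expect_identical(est$posterior_sd, 1)
})

test_that("EAP is monotone in any single response", {
  withr::with_seed(10, {
    for (rep in 1:10) {
      bank <- generate_item_bank(5, 4, seed = rep)
      row <- draw_row(bank, rnorm(1), seed = rep + 100)
      j <- sample(5, 1)
      eaps <- vapply(0:3, function(k) {
        r <- row; r[j] <- k
        estimate_theta_eap(r, bank)$theta
      }, numeric(1))
      expect_true(all(diff(eaps) > 0))
    }
  })
})

test_that("gauss-hermite and grid quadrature agree", {
  bank <- generate_item_bank(5, 5, seed = 12)
  row <- draw_row(bank, 0.4, seed = 3)
  g1 <- estimate_theta_eap(row, bank, quadrature_config(61))
  g2 <- estimate_theta_eap(row, bank,
                           quadrature_config(41, scheme = "gauss-hermite"))
  expect_equal(g1$theta, g2$theta, tolerance = 1e-6)
})
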