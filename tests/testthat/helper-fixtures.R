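# Shared fixtures: all generated in code at test time.

# a single well-behaved 3-category item used in closed-form checks
symmetric_item <- function() grm_item("sym", 1.5, c(-1, 1))

# clean GRM cohort (no low-quality responding, no group differences)
clean_sim <- function(n, n_items = 6, K = 6, seed = 1, bank_seed = 11) {
  bank <- generate_item_bank(n_items, K, seed = bank_seed, prefix = "q")
  cc <- cohort_config(
    n_respondents = n,
    scales = list(list(name = "s", n_items = n_items, n_categories = K)),
    careless_rate_normal = 0, careless_rate_impaired = 0,
    skip_rate_normal = 0, skip_rate_impaired = 0,
    trait_impairment_shift = 0, age_impairment_association = FALSE,
    seed = seed)
  sim <- simulate_cohort(cc, banks = list(s = bank))
  sim$true_bank <- bank
  sim
}

bank_discriminations <- function(bank)
  vapply(unclass(bank), `[[`, numeric(1), "discrimination")

bank_thresholds <- function(bank)
  unlist(lapply(unclass(bank), `[[`, "thresholds"))

# dense-grid posterior oracle for EAP (independent of the package's
# quadrature path: trapezoid integration on a fine grid)
eap_bruteforce <- function(row, bank, grid_n = 10001, lim = 8) {
  grid <- seq(-lim, lim, length.out = grid_n)
  loglik <- rep(0, grid_n)
  for (j in seq_along(bank)) {
    if (is.na(row[j])) next
    loglik <- loglik +
      log(category_probabilities(bank[[j]], grid)[, row[j] + 1])
  }
  post <- exp(loglik) * stats::dnorm(grid)
  z <- pracma::trapz(grid, post)
  m1 <- pracma::trapz(grid, grid * post) / z
  m2 <- pracma::trapz(grid, grid^2 * post) / z
  c(theta = m1, sd = sqrt(m2 - m1^2))
}

# draw one model-consistent response vector at a given theta
draw_row <- function(bank, theta, seed) {
  withr::with_seed(seed, {
    vapply(unclass(bank), function(it) {
      p <- category_probabilities(it, theta)
      sample(seq_along(p) - 1L, 1, prob = p)
    }, integer(1))
  })
}

# pair-counting oracle for the AUC: P(score_pos > score_neg) + half ties
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
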