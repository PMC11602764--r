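# Synthetic questionnaire cohorts with known graded-response structure,
# impairment labels, demographics, and injected low-quality responding.

.DEFAULT_SCALES <- list(
  list(name = "optimism", n_items = 6L, n_categories = 6L),
  list(name = "hopelessness", n_items = 7L, n_categories = 6L),
  list(name = "purpose", n_items = 7L, n_categories = 6L),
  list(name = "life_satisfaction", n_items = 5L, n_categories = 6L))

# age-bin probabilities and within-bin impairment prevalence pattern for a
# community sample of adults 50+ (bins 50-59 / 60-69 / 70-79 / 80+)
.AGE_BIN_PROBS <- c(0.207, 0.327, 0.312, 0.154)
.AGE_BIN_CI_PATTERN <- c(0.09, 0.122, 0.205, 0.387)

#' Configuration of a synthetic screening cohort
#'
#' Defaults describe the study conditions emulated throughout the package:
#' four brief well-being scales (6/7/7/5 items, six ordered categories),
#' 18\% impairment prevalence, ages 50+, roughly 1-2\% item missingness,
#' and low-quality-response behaviours (careless answering, skipping,
#' straight-lining) whose propensity is elevated among impaired
#' respondents.
#'
#' @param n_respondents cohort size (>= 2).
#' @param scales list of `list(name, n_items, n_categories)`.
#' @param prevalence overall impairment prevalence in (0, 1).
#' @param careless_rate_normal,careless_rate_impaired per-item probability
#'   of a careless answer, by impairment group.
#' @param skip_rate_normal,skip_rate_impaired per-item probability of a
#'   skipped (missing) answer, by group.
#' @param straightline_fraction share of careless acts that repeat the
#'   previous presented category instead of drawing a category uniformly.
#'   Straight-lining acts on the questionnaire as presented: on
#'   reverse-keyed items the repeated answer becomes a contradictory
#'   category code after recoding.
#' @param reverse_keyed if `TRUE` (default), every second item of each
#'   scale is reverse-worded, as in the brief well-being scales these
#'   cohorts emulate; stored responses are always on the recoded
#'   (construct-aligned) scale.
#' @param trait_impairment_shift mean latent-trait offset of the impaired
#'   group (content signal; 0 removes it).
#' @param age_impairment_association if `TRUE`, within-age-bin prevalence
#'   rises with age (rescaled to the overall `prevalence`); if `FALSE`, age
#'   and impairment are independent.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_respondents = 4000L,
                          scales = .DEFAULT_SCALES,
                          prevalence = 0.18,
                          careless_rate_normal = 0.05,
                          careless_rate_impaired = 0.30,
                          skip_rate_normal = 0.01,
                          skip_rate_impaired = 0.05,
                          straightline_fraction = 0.5,
                          reverse_keyed = TRUE,
                          trait_impairment_shift = -0.15,
                          age_impairment_association = TRUE,
                          seed = 1L) {
  if (!.is_count(n_respondents) || n_respondents < 2)
    stop("n_respondents must be an integer >= 2", call. = FALSE)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  rates <- c(careless_rate_normal, careless_rate_impaired,
             skip_rate_normal, skip_rate_impaired, straightline_fraction)
  if (!all(vapply(rates, .is_prob, logical(1))))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  stopifnot(is.list(scales), length(scales) >= 1L)
  scales <- lapply(scales, function(s) {
    stopifnot(is.character(s$name), .is_count(s$n_items),
              .is_count(s$n_categories), s$n_categories >= 2)
    list(name = s$name, n_items = as.integer(s$n_items),
         n_categories = as.integer(s$n_categories))
  })
  structure(list(
    n_respondents = as.integer(n_respondents), scales = scales,
    prevalence = prevalence,
    careless_rate_normal = careless_rate_normal,
    careless_rate_impaired = careless_rate_impaired,
    skip_rate_normal = skip_rate_normal,
    skip_rate_impaired = skip_rate_impaired,
    straightline_fraction = straightline_fraction,
    reverse_keyed = isTRUE(reverse_keyed),
    trait_impairment_shift = trait_impairment_shift,
    age_impairment_association = isTRUE(age_impairment_association),
    seed = as.integer(seed)), class = "cohort_config")
}

#' Generate item banks for every scale of a cohort configuration
#' @param config a [cohort_config()].
#' @return named list of `grm_item_bank`, one per scale.
#' @export
generate_scale_banks <- function(config) {
  seeds <- derive_seeds(config$seed, length(config$scales))
  banks <- lapply(seq_along(config$scales), function(i) {
    s <- config$scales[[i]]
    generate_item_bank(s$n_items, s$n_categories, seeds[i],
                       prefix = paste0(s$name, "_q"))
  })
  names(banks) <- vapply(config$scales, `[[`, character(1), "name")
  banks
}

.sample_ages <- function(n) {
  bin <- sample.int(4L, n, replace = TRUE, prob = .AGE_BIN_PROBS)
  lo <- c(50, 60, 70, 80)[bin]
  hi <- c(60, 70, 80, 96)[bin]
  round(lo + stats::runif(n) * (hi - lo), 1)
}

.age_bin <- function(age) {
  cut(age, c(-Inf, 60, 70, 80, Inf), right = FALSE,
      labels = c("50-59", "60-69", "70-79", "80+"))
}

#' Simulate a questionnaire cohort with injected low-quality responding
#'
#' Each respondent draws a latent trait `Normal(shift * impaired, 1)`. For
#' every item, the answer is skipped with the group's skip rate; otherwise,
#' with the group's careless rate, a careless category is emitted (repeat of
#' the previous emitted category with probability `straightline_fraction`,
#' else uniform over categories); otherwise the category is drawn from the
#' graded response model. Demographics (age, gender), disease indicators
#' used by rule-based screening comparators, impairment labels and an
#' optional 10-year dementia-or-mortality label are attached, together with
#' the simulation truth (`true_theta`, `true_careless`).
#'
#' @param config a [cohort_config()].
#' @param banks optional named list of item banks per scale; generated from
#'   the config seed when `NULL`.
#' @return list with `responses` (a [response_matrix()]), `cohort` (data
#'   frame, one row per respondent) and `banks`.
#' @export
simulate_cohort <- function(config, banks = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(banks)) banks <- generate_scale_banks(config)
  scale_names <- vapply(config$scales, `[[`, character(1), "name")
  stopifnot(identical(sort(names(banks)), sort(scale_names)))
  n <- config$n_respondents
  .with_seed(derive_seeds(config$seed, 2L)[2L], {
    age <- .sample_ages(n)
    gender <- stats::rbinom(n, 1, 0.57)  # 1 = female
    if (config$age_impairment_association) {
      bin <- as.integer(.age_bin(age))
      mix <- sum(.AGE_BIN_PROBS * .AGE_BIN_CI_PATTERN)
      p_ci <- .clip(.AGE_BIN_CI_PATTERN[bin] * config$prevalence / mix,
                    0, 0.95)
    } else {
      p_ci <- rep(config$prevalence, n)
    }
    impairment <- stats::rbinom(n, 1, p_ci)
    theta <- stats::rnorm(n, config$trait_impairment_shift * impairment, 1)
    careless_rate <- ifelse(impairment == 1, config$careless_rate_impaired,
                            config$careless_rate_normal)
    skip_rate <- ifelse(impairment == 1, config$skip_rate_impaired,
                        config$skip_rate_normal)

    items <- do.call(c, lapply(scale_names, function(s) unclass(banks[[s]])))
    item_scale <- rep(scale_names,
                      vapply(config$scales, `[[`, integer(1), "n_items"))
    J <- length(items)
    # every second item of each scale is reverse-keyed (when enabled)
    within_scale_pos <- unlist(lapply(
      vapply(config$scales, `[[`, integer(1), "n_items"), seq_len))
    reversed <- config$reverse_keyed & within_scale_pos %% 2L == 0L
    values <- matrix(NA_integer_, n, J)
    prev_pres <- rep(NA_integer_, n)  # last presented category
    careless_any <- rep(FALSE, n)
    for (j in seq_len(J)) {
      it <- items[[j]]
      K <- it$n_categories
      pmat <- t(.grm_prob_mat(it$discrimination, it$thresholds, theta))
      cum <- t(apply(pmat, 1, cumsum))
      u <- stats::runif(n)
      grm_draw <- pmin(rowSums(cum < u), K - 1L)  # recoded scale
      # careless alternatives: straight-lining repeats the previous
      # *presented* answer, so it contradicts reverse-keyed items
      uniform_draw <- sample.int(K, n, replace = TRUE) - 1L
      straight_pres <- ifelse(is.na(prev_pres), uniform_draw,
                              pmin(prev_pres, K - 1L))
      straight <- if (reversed[j]) K - 1L - straight_pres else straight_pres
      is_straight <- stats::runif(n) < config$straightline_fraction
      careless_draw <- ifelse(is_straight, straight, uniform_draw)
      r_skip <- stats::runif(n) < skip_rate
      r_careless <- stats::runif(n) < careless_rate
      cat_j <- as.integer(ifelse(r_careless, careless_draw, grm_draw))
      cat_j[r_skip] <- NA_integer_
      values[, j] <- cat_j
      pres_j <- if (reversed[j]) K - 1L - cat_j else cat_j
      prev_pres <- ifelse(is.na(pres_j), prev_pres, pres_j)
      careless_any <- careless_any | (r_careless & !r_skip)
    }

    disease <- function(intercept) stats::rbinom(n, 1,
      stats::plogis(intercept + 0.05 * age))
    future_event <- stats::rbinom(n, 1,
      stats::plogis(-1.8 + 1.2 * impairment + 0.06 * (age - 70)))

    cohort <- data.frame(
      respondent_id = sprintf("r%05d", seq_len(n)),
      age = age, gender = gender, impairment = impairment,
      future_event = future_event,
      high_blood_pressure = disease(-3.3),
      diabetes = disease(-4.9),
      heart_disease = disease(-4.6),
      stroke = disease(-6.1),
      true_theta = theta, true_careless = as.integer(careless_any),
      stringsAsFactors = FALSE)

    rownames(values) <- cohort$respondent_id
    colnames(values) <- vapply(items, `[[`, character(1), "item_id")
    responses <- response_matrix(
      values, vapply(items, `[[`, integer(1), "n_categories"), item_scale)
    list(responses = responses, cohort = cohort, banks = banks)
  })
}

#' Attach cognition scores consistent with the impairment labels
#'
#' Impaired respondents draw a score uniformly from the impaired band
#' (0-11: dementia 0-6 or cognitive impairment without dementia 7-11);
#' unimpaired respondents draw uniformly from 12-27. Deriving the binary
#' label back from the score reproduces `impairment` exactly.
#'
#' @param cohort cohort data frame with an `impairment` column.
#' @param seed integer seed.
#' @return the cohort with a `cognition_score` column.
#' @export
assign_cognition_scores <- function(cohort, seed = 1L) {
  stopifnot("impairment" %in% names(cohort))
  .with_seed(seed, {
    n <- nrow(cohort)
    score <- ifelse(cohort$impairment == 1,
                    sample(0:11, n, replace = TRUE),
                    sample(12:27, n, replace = TRUE))
    cohort$cognition_score <- as.integer(score)
    cohort
  })
}
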