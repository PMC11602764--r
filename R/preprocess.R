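# Outcome-label derivation, regression-based iterative imputation, and
# prevalence-matched train/test splitting.

#' Map cognition scores to impairment categories (Langa-Weir bands)
#'
#' Scores 0-27 partition into dementia (0-6), cognitive impairment without
#' dementia (7-11) and normal (12-27); the binary cognitive-impairment
#' label combines the first two bands.
#'
#' @param score integer vector of cognition scores in `[0, 27]`.
#' @return data frame with columns `cognition_score`, `category`
#'   (factor: `dementia`, `cind`, `normal`) and `binary_ci` (logical).
#' @export
derive_ci_label <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(score != round(score)) ||
      any(score < 0 | score > 27))
    stop("cognition scores must be integers in [0, 27]", call. = FALSE)
  category <- cut(score, c(-1, 6, 11, 27),
                  labels = c("dementia", "cind", "normal"))
  data.frame(cognition_score = as.integer(score), category = category,
             binary_ci = category != "normal")
}

#' Regression-based iterative imputation
#'
#' Round-robin chained regression: after a column-median initialisation,
#' every variable with missing entries is regressed (ordinary least
#' squares) on all other variables and its missing cells replaced by the
#' fitted values, iterating until the mean absolute change of the imputed
#' cells drops below `tol` or `max_iter` is reached. Observed entries are
#' never altered. When `round_to` bounds are supplied (the
#' `response_matrix` method sets them from the item category ranges),
#' imputed values are rounded and clipped at the end.
#'
#' @param tab numeric data frame / matrix with missing values, or a
#'   [response_matrix()].
#' @param max_iter maximum sweeps over the columns.
#' @param tol convergence tolerance on the imputed cells.
#' @param seed accepted for interface symmetry; the imputation itself is
#'   deterministic.
#' @param ... passed between methods.
#' @return completed object of the same shape, with no missing values.
#' @export
iterative_impute <- function(tab, max_iter = 10L, tol = 1e-3, seed = 1L,
                             ...) {
  UseMethod("iterative_impute")
}

#' @rdname iterative_impute
#' @param round_to optional 2 x p matrix of lower/upper integer bounds per
#'   column; columns with bounds are rounded and clipped after convergence.
#' @export
iterative_impute.default <- function(tab, max_iter = 10L, tol = 1e-3,
                                     seed = 1L, round_to = NULL, ...) {
  df <- as.matrix(tab)
  storage.mode(df) <- "double"
  miss <- is.na(df)
  if (!any(miss)) return(tab)
  all_gone <- which(colSums(!miss) == 0L)
  if (length(all_gone))
    stop(sprintf("column '%s' is entirely missing and cannot be imputed",
                 (colnames(df) %||% as.character(all_gone))[all_gone[1]]),
         call. = FALSE)
  # median initialisation
  for (j in which(colSums(miss) > 0L))
    df[miss[, j], j] <- stats::median(df[!miss[, j], j])
  targets <- which(colSums(miss) > 0L)
  for (iter in seq_len(max_iter)) {
    delta <- 0; cells <- 0L
    for (j in targets) {
      y <- df[, j]
      X <- cbind(1, df[, -j, drop = FALSE])
      obs <- !miss[, j]
      fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(X[miss[, j], , drop = FALSE] %*% beta)
      delta <- delta + sum(abs(pred - df[miss[, j], j]))
      cells <- cells + length(pred)
      df[miss[, j], j] <- pred
    }
    if (delta / cells < tol) break
  }
  if (!is.null(round_to)) {
    for (j in seq_len(ncol(df))) {
      if (anyNA(round_to[, j])) next
      v <- df[miss[, j], j]
      df[miss[, j], j] <- .clip(round(v), round_to[1, j], round_to[2, j])
    }
  }
  if (is.data.frame(tab)) {
    out <- as.data.frame(df)
    names(out) <- names(tab)
    out
  } else df
}

#' @rdname iterative_impute
#' @export
iterative_impute.response_matrix <- function(tab, max_iter = 10L,
                                             tol = 1e-3, seed = 1L, ...) {
  k <- itemCategories(tab)
  bounds <- rbind(rep(0L, ncol(tab)), k - 1L)
  filled <- iterative_impute.default(unclass(as.matrix(tab)),
                                     max_iter = max_iter, tol = tol,
                                     seed = seed, round_to = bounds)
  response_matrix(filled, k, itemScales(tab))
}

#' Specification of a prevalence-matched train/test split
#'
#' @param test_fraction fraction held out for testing (default 0.30).
#' @param stratify_on label column used for stratification.
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.30, stratify_on = "impairment",
                       seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(test_fraction = test_fraction, stratify_on = stratify_on,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/test split with matched outcome prevalence
#'
#' Respondents are allocated per label stratum so that the held-out
#' fraction — and hence the impairment prevalence — matches between the
#' partitions up to integer rounding. Deterministic given the seed.
#'
#' @param cohort cohort data frame with a `respondent_id` column and the
#'   stratification label.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` (respondent ids) and `manifest`
#'   (data frame `respondent_id`, `partition`).
#' @export
stratified_split <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"),
            spec$stratify_on %in% names(cohort),
            "respondent_id" %in% names(cohort))
  lab <- cohort[[spec$stratify_on]]
  ids <- cohort$respondent_id
  .with_seed(spec$seed, {
    test_ids <- character(0)
    for (g in sort(unique(lab))) {
      members <- ids[lab == g]
      if (length(members) < 2L) {
        warning(sprintf(
          "stratum '%s' has fewer than 2 members; assigned to train", g))
        next
      }
      n_test <- round(spec$test_fraction * length(members))
      test_ids <- c(test_ids, sample(members, n_test))
    }
    train_ids <- setdiff(ids, test_ids)
    manifest <- data.frame(
      respondent_id = ids,
      partition = ifelse(ids %in% test_ids, "test", "train"),
      stringsAsFactors = FALSE)
    list(train = train_ids, test = sort(test_ids), manifest = manifest)
  })
}
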