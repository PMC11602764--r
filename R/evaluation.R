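# Discrimination and screening-efficiency metrics, rule-based comparator
# strategies, and age-stratified reports.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random impaired respondent scores above a random
#' unimpaired one, with half credit for ties (midranks).
#'
#' @param scores risk scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- .check_labels(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screening-efficiency curve
#'
#' For every candidate threshold: the proportion of all individuals
#' referred for follow-up assessment (resources required) against the
#' proportion of impaired individuals identified (screening yield) — the
#' positive rate and sensitivity of the referral rule. Sorted by
#' threshold; the point at threshold 0 approaches (1, 1) and the point at
#' threshold 1 is (0, 0).
#'
#' @inheritParams auc
#' @return data frame of class `efficiency_curve` with columns
#'   `threshold`, `proportion_referred`, `proportion_identified`.
#' @export
efficiency_curve <- function(scores, labels) {
  y <- .check_labels(labels)
  stopifnot(length(scores) == length(y))
  cand <- candidate_thresholds(scores)
  pr <- vapply(cand, function(t) mean(scores > t), numeric(1))
  pi_ <- vapply(cand, function(t) mean(scores[y == 1] > t), numeric(1))
  structure(data.frame(threshold = cand, proportion_referred = pr,
                       proportion_identified = pi_),
            class = c("efficiency_curve", "data.frame"))
}

#' Rule-based screening strategy
#'
#' A deterministic predicate over cohort attributes. Built-in rules:
#' `age65` (age >= 65), `diabetes`, `high_blood_pressure`,
#' `heart_disease`, `stroke` (each refers the respondents with the
#' indicator set).
#'
#' @param name rule name; one of the built-ins unless `predicate` is
#'   given.
#' @param predicate optional function of the cohort data frame returning a
#'   logical vector.
#' @param requires attributes the predicate needs.
#' @return object of class `rule_strategy`.
#' @export
rule_strategy <- function(name, predicate = NULL, requires = NULL) {
  if (is.null(predicate)) {
    builtin <- list(
      age65 = list(function(d) d$age >= 65, "age"),
      diabetes = list(function(d) d$diabetes == 1, "diabetes"),
      high_blood_pressure = list(function(d) d$high_blood_pressure == 1,
                                 "high_blood_pressure"),
      heart_disease = list(function(d) d$heart_disease == 1,
                           "heart_disease"),
      stroke = list(function(d) d$stroke == 1, "stroke"))
    if (!name %in% names(builtin))
      stop(sprintf("unknown built-in rule '%s' (available: %s)", name,
                   paste(names(builtin), collapse = ", ")), call. = FALSE)
    predicate <- builtin[[name]][[1]]
    requires <- builtin[[name]][[2]]
  }
  structure(list(name = name, predicate = predicate,
                 requires = requires %||% character(0)),
            class = "rule_strategy")
}

#' Efficiency point of a rule-based screening strategy
#'
#' @param cohort cohort data frame with an `impairment` column and the
#'   attributes the rule requires.
#' @param rule a [rule_strategy()] or built-in rule name.
#' @return named numeric: `proportion_referred` (fraction of the cohort
#'   the rule refers) and `proportion_identified` (fraction of impaired
#'   respondents it refers).
#' @export
rule_point <- function(cohort, rule) {
  if (is.character(rule)) rule <- rule_strategy(rule)
  stopifnot(inherits(rule, "rule_strategy"),
            "impairment" %in% names(cohort))
  missing_attr <- setdiff(rule$requires, names(cohort))
  if (length(missing_attr))
    stop(sprintf("cohort lacks attribute(s) required by rule '%s': %s",
                 rule$name, paste(missing_attr, collapse = ", ")),
         call. = FALSE)
  sel <- rule$predicate(cohort)
  if (anyNA(sel)) stop("rule predicate returned missing values",
                       call. = FALSE)
  c(proportion_referred = mean(sel),
    proportion_identified = mean(sel[cohort$impairment == 1]))
}

#' Age-stratified performance and efficiency report
#'
#' AUC, referral and identification proportions per decade age group
#' (50-59, 60-69, 70-79, 80+) at the threshold selected globally by the
#' cost ratio, plus the overall row. A single-class age group gets a
#' missing AUC rather than a placeholder.
#'
#' @param scores risk scores on the evaluated individuals.
#' @param labels binary 0/1 impairment labels.
#' @param cohort cohort rows for the same individuals (needs `age`).
#' @param cost_ratio underdiagnosis/overdiagnosis cost ratio used to pick
#'   the global threshold.
#' @param threshold optional externally selected threshold; when supplied
#'   (e.g. tuned on validation predictions), it is used as-is.
#' @return object of class `evaluation_report`.
#' @export
stratified_report <- function(scores, labels, cohort, cost_ratio = 4,
                              threshold = NULL) {
  y <- .check_labels(labels)
  stopifnot("age" %in% names(cohort), nrow(cohort) == length(y))
  decision <- if (is.null(threshold))
    select_threshold(scores, y, cost_ratio)
  else {
    thr_ref <- scores > threshold
    structure(list(threshold = threshold, cost_ratio = cost_ratio,
                   total_cost = cost_ratio * sum(y == 1 & !thr_ref) +
                     sum(y == 0 & thr_ref),
                   confusion = c(tp = sum(y == 1 & thr_ref),
                                 fp = sum(y == 0 & thr_ref),
                                 fn = sum(y == 1 & !thr_ref),
                                 tn = sum(y == 0 & !thr_ref)),
                   n_referred = sum(thr_ref),
                   n_cases_identified = sum(y == 1 & thr_ref),
                   proportion_referred = mean(thr_ref),
                   proportion_identified = mean(thr_ref[y == 1])),
              class = "threshold_decision")
  }
  ref <- scores > decision$threshold
  bins <- .age_bin(cohort$age)
  rows <- lapply(levels(bins), function(b) {
    in_b <- bins == b
    n <- sum(in_b)
    if (n == 0L)
      return(data.frame(age_group = b, n = 0L, n_impaired = 0L,
                        auc = NA_real_, n_referred = 0L,
                        n_identified = 0L,
                        proportion_referred = NA_real_,
                        proportion_identified = NA_real_))
    yb <- y[in_b]
    auc_b <- if (length(unique(yb)) == 2L) auc(scores[in_b], yb)
             else NA_real_
    data.frame(age_group = b, n = n, n_impaired = sum(yb),
               auc = auc_b, n_referred = sum(ref[in_b]),
               n_identified = sum(ref[in_b] & yb == 1),
               proportion_referred = mean(ref[in_b]),
               proportion_identified = if (sum(yb) > 0)
                 mean(ref[in_b][yb == 1]) else NA_real_)
  })
  by_age <- do.call(rbind, rows)
  structure(list(auc = auc(scores, y), decision = decision,
                 by_age_group = by_age,
                 overall = data.frame(
                   n = length(y), n_impaired = sum(y),
                   n_referred = sum(ref),
                   n_identified = decision$n_cases_identified)),
            class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> AUC %.3f; threshold %.4f (cost ratio %.3g)\n",
    x$auc, x$decision$threshold, x$decision$cost_ratio))
  df <- x$by_age_group
  df$auc <- round(df$auc, 3)
  df$proportion_referred <- round(100 * df$proportion_referred, 1)
  df$proportion_identified <- round(100 * df$proportion_identified, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to JSON (full precision)
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(auc = report$auc,
              decision = unclass(report$decision),
              by_age_group = report$by_age_group,
              overall = report$overall)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
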