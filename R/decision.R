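# Referral decisions: cost-ratio threshold selection.

#' Candidate thresholds for a score vector
#'
#' Midpoints between adjacent distinct sorted scores, together with 0
#' and 1. Both threshold selection and the efficiency curve use this set,
#' so the two agree pointwise.
#'
#' @param scores risk scores in `[0, 1]`.
#' @return increasing numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  sort(unique(c(0, mids, 1)))
}

#' Referral rule: refer exactly the scores above the threshold
#'
#' Strict inequality: a score equal to the threshold is not referred.
#'
#' @param scores risk scores.
#' @param threshold referral threshold in `[0, 1]`.
#' @return logical vector.
#' @export
refer <- function(scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  scores > threshold
}

#' Select the referral threshold by the underdiagnosis cost ratio
#'
#' Underdiagnosis (a false negative: an impaired individual classified
#' normal) costs `cost_ratio` times one overdiagnosis (a false positive:
#' one unnecessary follow-up assessment). The threshold minimising
#' `cost_ratio * FN(t) + FP(t)` over [candidate_thresholds()] is chosen;
#' cost ties break toward the largest threshold (fewest referrals).
#'
#' @param scores risk scores in `[0, 1]`.
#' @param labels binary 0/1 impairment labels (both classes present).
#' @param cost_ratio positive underdiagnosis/overdiagnosis cost ratio
#'   (default 4).
#' @return object of class `threshold_decision` with the threshold, its
#'   confusion counts, total cost, and referral summaries.
#' @export
select_threshold <- function(scores, labels, cost_ratio = 4) {
  stopifnot(is.numeric(scores), all(scores >= 0 & scores <= 1))
  y <- .check_labels(labels)
  if (!is.numeric(cost_ratio) || length(cost_ratio) != 1L ||
      cost_ratio <= 0)
    stop("cost_ratio must be a single positive number", call. = FALSE)
  cand <- candidate_thresholds(scores)
  # counts above each candidate, via cumulative sums on sorted scores
  n_pos <- sum(y == 1)
  costs <- vapply(cand, function(t) {
    ref <- scores > t
    fn <- sum(y == 1 & !ref)
    fp <- sum(y == 0 & ref)
    cost_ratio * fn + fp
  }, numeric(1))
  best <- max(which(costs == min(costs)))  # largest threshold on ties
  thr <- cand[best]
  ref <- scores > thr
  fn <- sum(y == 1 & !ref); fp <- sum(y == 0 & ref)
  tp <- sum(y == 1 & ref); tn <- sum(y == 0 & !ref)
  structure(list(threshold = thr, cost_ratio = cost_ratio,
                 total_cost = cost_ratio * fn + fp,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 n_referred = sum(ref), n_cases_identified = tp,
                 proportion_referred = mean(ref),
                 proportion_identified = tp / n_pos),
            class = "threshold_decision")
}

#' @exportS3Method base::print
print.threshold_decision <- function(x, ...) {
  cat(sprintf(paste0(
    "<threshold_decision> cost ratio %.3g -> threshold %.4f\n",
    "  total cost %.1f; referred %d (%.1f%%), impaired identified %d",
    " (%.1f%%)\n"),
    x$cost_ratio, x$threshold, x$total_cost, x$n_referred,
    100 * x$proportion_referred, x$n_cases_identified,
    100 * x$proportion_identified))
  invisible(x)
}

#' Write a threshold decision to JSON
#' @param decision a `threshold_decision`.
#' @param path output file.
#' @export
write_decision <- function(decision, path) {
  stopifnot(inherits(decision, "threshold_decision"))
  jsonlite::write_json(unclass(decision), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
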