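# Low-quality-response indices derived from a fitted graded response model.

.check_row_bank <- function(values, bank) {
  if (ncol(values) != length(bank))
    stop(sprintf("bank has %d items but responses have %d columns",
                 length(bank), ncol(values)), call. = FALSE)
}

#' Squared-residual low-quality-response index
#'
#' Per respondent and item, the squared difference between the observed
#' category and the model-expected response given the respondent's latent
#' trait: `s_ij = (x_ij - E[X_i | theta_j])^2`. Large values flag answers
#' far from what the trait predicts. Missing responses give missing
#' indices.
#'
#' @param responses a [response_matrix()] (or matrix / single row).
#' @param bank `grm_item_bank` matching the columns.
#' @param traits data frame from [estimate_theta_eap()] for the same rows
#'   and bank.
#' @return numeric matrix, respondents x items.
#' @export
squared_residual_index <- function(responses, bank, traits) {
  if (is.null(dim(responses))) responses <- rbind(responses)
  values <- unclass(as.matrix(responses))
  .check_row_bank(values, bank)
  stopifnot(nrow(values) == nrow(traits))
  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_along(bank)) {
    e <- expected_response(bank[[j]], traits$theta)
    out[, j] <- (values[, j] - e)^2
  }
  out
}

#' Response-probability low-quality-response index
#'
#' Per respondent and item, the model probability of the category actually
#' chosen given the latent trait: `p_ij = P_{i, x_ij}(theta_j)`, in
#' `(0, 1]`. Improbable answers flag low-quality responding. Missing
#' responses give missing indices.
#'
#' @inheritParams squared_residual_index
#' @return numeric matrix, respondents x items.
#' @export
response_probability_index <- function(responses, bank, traits) {
  if (is.null(dim(responses))) responses <- rbind(responses)
  values <- unclass(as.matrix(responses))
  .check_row_bank(values, bank)
  stopifnot(nrow(values) == nrow(traits))
  out <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_along(bank)) {
    it <- bank[[j]]
    pm <- t(.grm_prob_mat(it$discrimination, it$thresholds, traits$theta))
    x <- values[, j]
    obs <- which(!is.na(x))
    out[obs, j] <- pm[cbind(obs, x[obs] + 1L)]
  }
  pmax(out, .PMIN)
}

#' Assemble the predictor table of low-quality-response features
#'
#' For each selected scale the latent trait is scored from that scale's own
#' items (one unidimensional model per questionnaire) and both indices are
#' computed, giving two feature columns per item (`sr_*`, `rp_*`) — or, in
#' aggregate mode, per-scale means (mean squared residual and mean (log)
#' response probability). Demographics append `age` and `gender`.
#' Combining several scales concatenates their features.
#'
#' @param responses a [response_matrix()] with scale assignments.
#' @param banks named list of fitted `grm_item_bank`, one per scale.
#' @param cohort cohort data frame (required for demographics).
#' @param scales scales to include (default: all fitted banks).
#' @param include_demographics append `age` and `gender` columns.
#' @param aggregate use per-scale mean indices instead of per-item columns.
#' @param log_probability use `log(p_ij)` for the probability index.
#' @param traits optional named list of precomputed trait tables per scale.
#' @param quad a [quadrature_config()].
#' @return data frame of features with attribute `layout` describing the
#'   columns; row order follows `responses`.
#' @export
build_feature_table <- function(responses, banks, cohort = NULL,
                                scales = names(banks),
                                include_demographics = FALSE,
                                aggregate = FALSE, log_probability = FALSE,
                                traits = NULL,
                                quad = quadrature_config()) {
  stopifnot(inherits(responses, "response_matrix"))
  available <- unique(itemScales(responses))
  unknown <- setdiff(scales, available)
  if (length(unknown))
    stop(sprintf("unknown scale(s): %s (available: %s)",
                 paste(unknown, collapse = ", "),
                 paste(available, collapse = ", ")), call. = FALSE)
  if (!all(scales %in% names(banks)))
    stop("no fitted bank for scale(s): ",
         paste(setdiff(scales, names(banks)), collapse = ", "),
         call. = FALSE)
  cols <- list()
  for (s in scales) {
    sub <- scaleItems(responses, s)
    bank <- banks[[s]]
    tr <- if (!is.null(traits)) traits[[s]] else
      estimate_theta_eap(sub, bank, quad)
    sr <- squared_residual_index(sub, bank, tr)
    rp <- response_probability_index(sub, bank, tr)
    if (log_probability) rp <- log(rp)
    if (aggregate) {
      cols[[paste0("sr_mean_", s)]] <- rowMeans(sr, na.rm = TRUE)
      cols[[paste0("rp_mean_", s)]] <- rowMeans(rp, na.rm = TRUE)
    } else {
      for (j in seq_len(ncol(sr))) {
        cols[[paste0("sr_", colnames(sr)[j])]] <- sr[, j]
        cols[[paste0("rp_", colnames(rp)[j])]] <- rp[, j]
      }
    }
  }
  if (include_demographics) {
    if (is.null(cohort) || !all(c("age", "gender") %in% names(cohort)))
      stop("demographics requested but cohort lacks age/gender",
           call. = FALSE)
    stopifnot(nrow(cohort) == nrow(responses))
    cols$age <- cohort$age
    cols$gender <- cohort$gender
  }
  out <- as.data.frame(cols, row.names = rownames(responses),
                       optional = TRUE)
  attr(out, "layout") <- list(scales = scales, aggregate = aggregate,
                              log_probability = log_probability,
                              demographics = include_demographics,
                              columns = names(out))
  out
}
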