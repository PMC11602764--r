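# CSV / JSON / YAML interchange for responses, cohorts and run
# configuration.

#' Write questionnaire responses to CSV
#'
#' One row per respondent, one column per item, empty cells for missing
#' answers; the first column holds the respondent id. Category counts and
#' scale assignments go to a JSON sidecar (`<path>.schema.json`) so the
#' matrix round-trips exactly, including the missing mask.
#'
#' @param responses a [response_matrix()].
#' @param path output CSV path.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_matrix"))
  df <- data.frame(respondent_id = rownames(responses),
                   unclass(as.matrix(responses)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  schema <- list(items = colnames(responses),
                 n_categories = itemCategories(responses),
                 scales = itemScales(responses))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read questionnaire responses from CSV
#'
#' Expects the layout of [write_responses()]. Cells must be integers
#' within the declared category range; violations are reported with their
#' row and column. Duplicate respondent ids and empty files are errors.
#'
#' @param path CSV path.
#' @param n_categories per-item category counts; read from the schema
#'   sidecar when `NULL` and one exists, otherwise inferred from the data.
#' @param scales optional per-item scale names (sidecar wins when present).
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, n_categories = NULL, scales = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop(sprintf("'%s' contains no responses", path), call. = FALSE)
  if (names(df)[1] != "respondent_id")
    stop("first column must be 'respondent_id'", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate respondent_id '%s' (row %d)",
                 ids[anyDuplicated(ids)], anyDuplicated(ids)),
         call. = FALSE)
  schema_path <- paste0(path, ".schema.json")
  if (is.null(n_categories) && file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    n_categories <- schema$n_categories
    scales <- scales %||% schema$scales
  }
  vals <- matrix(NA_integer_, nrow(df), ncol(df) - 1L,
                 dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(vals))) {
    raw <- trimws(df[[j + 1L]])
    filled <- which(raw != "" & !is.na(raw))
    num <- suppressWarnings(as.numeric(raw[filled]))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad))
      stop(sprintf("non-integer response '%s' at row %d, column '%s'",
                   raw[filled][bad[1]], filled[bad[1]],
                   colnames(vals)[j]), call. = FALSE)
    vals[filled, j] <- as.integer(num)
  }
  if (is.null(n_categories))
    n_categories <- apply(vals, 2, function(v)
      max(v, na.rm = TRUE) + 1L)
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    bad <- which(!is.na(v) & (v < 0L | v >= n_categories[j]))
    if (length(bad))
      stop(sprintf(
        "out-of-range code %d at row %d, column '%s' (valid: 0-%d)",
        v[bad[1]], bad[1], colnames(vals)[j], n_categories[j] - 1L),
        call. = FALSE)
  }
  response_matrix(vals, n_categories, scales)
}

#' Write / read a cohort table as CSV
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.RUN_CONFIG_DEFAULTS <- list(
  n_respondents = 4000L, prevalence = 0.18,
  careless_rate_normal = 0.05, careless_rate_impaired = 0.30,
  skip_rate_normal = 0.01, skip_rate_impaired = 0.05,
  straightline_fraction = 0.5, reverse_keyed = TRUE,
  trait_impairment_shift = -0.15, age_impairment_association = TRUE,
  scale = "optimism", include_demographics = TRUE,
  aggregate = FALSE, log_probability = FALSE,
  model = "mlp", cost_ratio = 4, test_fraction = 0.30, seed = 1L,
  mlp_max_epochs = 200L, cv_folds = 10L)

#' Build and validate an end-to-end run configuration
#'
#' Unknown keys are rejected and value constraints checked before any
#' computation. See [run_pipeline()] for the meaning of each field.
#'
#' @param ... named overrides of the defaults.
#' @return validated configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(.RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  config <- utils::modifyList(.RUN_CONFIG_DEFAULTS, overrides)
  if (!is.numeric(config$cost_ratio) || config$cost_ratio <= 0)
    stop("cost_ratio must be a positive number", call. = FALSE)
  if (!config$model %in% c("mlp", "logistic", "tree",
                           "gradient_boosting", "raw_response"))
    stop(sprintf("unknown model kind '%s'", config$model), call. = FALSE)
  if (config$test_fraction <= 0 || config$test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  rates <- config[c("careless_rate_normal", "careless_rate_impaired",
                    "skip_rate_normal", "skip_rate_impaired",
                    "straightline_fraction")]
  if (!all(vapply(rates, .is_prob, logical(1))))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (config$prevalence <= 0 || config$prevalence >= 1)
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  structure(config, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file of configuration keys.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  run_config(yaml::read_yaml(path))
}
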