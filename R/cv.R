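# Cross-validation layout shared by the MLP and the baseline learners.

#' Cross-validation configuration
#'
#' The training data are partitioned into `n_folds` folds. In repeat `j`,
#' the validation subset is the block of consecutive folds (wrapping)
#' covering `inner_validation_fraction` of the data, and the model trains
#' on the remaining folds — an 80/20 inner split per repeat with the
#' defaults. The repeat whose validation AUC is highest supplies the
#' retained model.
#'
#' @param n_folds number of folds (default 10).
#' @param inner_validation_fraction validation share per repeat
#'   (default 0.20).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, inner_validation_fraction = 0.20) {
  if (!.is_count(n_folds) || n_folds < 2)
    stop("n_folds must be an integer >= 2", call. = FALSE)
  k_val <- max(1L, round(inner_validation_fraction * n_folds))
  if (k_val >= n_folds)
    stop("inner_validation_fraction leaves no training folds",
         call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 inner_validation_fraction = inner_validation_fraction,
                 k_val = k_val),
            class = "cv_config")
}

# fold id per row (stratified by label), deterministic given seed
.make_folds <- function(labels, n_folds, seed) {
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# validation fold ids of repeat j: k_val consecutive folds, wrapping
.val_folds <- function(j, cv) ((j - 1L + seq_len(cv$k_val) - 1L) %%
                                 cv$n_folds) + 1L

.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 without missing values", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; both classes are required",
         call. = FALSE)
  labels
}

.check_features <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop("features contain missing values; impute first (iterative_impute)",
         call. = FALSE)
  x
}
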