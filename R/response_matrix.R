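#' Respondent-by-item response matrix
#'
#' Integer category codes in `0 ... K_i - 1` with `NA` marking skipped or
#' "do not know" answers. Per-item category counts and the scale each item
#' belongs to travel with the matrix as attributes.
#'
#' @param values integer matrix, respondents in rows, items in columns;
#'   `NA` = missing. Row and column names become respondent and item ids.
#' @param n_categories integer vector, `K` per item (recycled if length 1).
#' @param scales optional character vector naming each item's scale
#'   (recycled if length 1).
#' @return object of class `response_matrix` (an integer matrix).
#' @export
response_matrix <- function(values, n_categories, scales = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 1L || nrow(values) < 1L)
    stop("response matrix must have at least one row and one column",
         call. = FALSE)
  storage.mode(values) <- "integer"
  n_categories <- as.integer(rep_len(n_categories, ncol(values)))
  if (any(n_categories < 2L))
    stop("every item needs at least 2 categories", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("item%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("r%05d", seq_len(nrow(values)))
  dimnames(values) <- list(unname(rownames(values)),
                           unname(colnames(values)))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0L | v >= n_categories[j]))
    if (length(bad))
      stop(sprintf(
        "response out of range for item '%s' (row %d, value %d, K = %d)",
        colnames(values)[j], bad[1], v[bad[1]], n_categories[j]),
        call. = FALSE)
  }
  if (!is.null(scales)) scales <- rep_len(as.character(scales), ncol(values))
  structure(values, n_categories = n_categories, scales = scales,
            class = c("response_matrix", class(values)))
}

#' Number of response categories per item
#' @param x a `response_matrix`.
#' @export
itemCategories <- function(x) {
  k <- attr(x, "n_categories")
  if (is.null(k)) k <- apply(x, 2, function(v) max(v, na.rm = TRUE) + 1L)
  as.integer(k)
}

#' Scale membership per item
#' @param x a `response_matrix`.
#' @export
itemScales <- function(x) attr(x, "scales")

#' Subset a response matrix to the items of one scale
#' @param x a `response_matrix`.
#' @param scale scale name (must appear in `itemScales(x)`).
#' @export
scaleItems <- function(x, scale) {
  sc <- itemScales(x)
  if (is.null(sc)) stop("response matrix carries no scale assignment",
                        call. = FALSE)
  keep <- which(sc == scale)
  if (!length(keep))
    stop(sprintf("unknown scale '%s' (available: %s)", scale,
                 paste(unique(sc), collapse = ", ")), call. = FALSE)
  response_matrix(unclass(x)[, keep, drop = FALSE],
                  itemCategories(x)[keep], sc[keep])
}

#' @exportS3Method base::print
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  sc <- itemScales(x)
  if (!is.null(sc))
    cat("  scales:", paste(sprintf("%s (%d)", unique(sc),
                                   tabulate(factor(sc, unique(sc)))),
                           collapse = ", "), "\n")
  invisible(x)
}
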