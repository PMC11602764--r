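#' Item parameters for the graded response model
#'
#' A single polytomous item is described by a positive logistic
#' discrimination and `K - 1` strictly increasing category thresholds on the
#' latent-trait scale. Categories are coded `0 ... K - 1` throughout.
#'
#' @param item_id character identifier.
#' @param discrimination positive slope of the cumulative logistic curves.
#' @param thresholds numeric vector of length `K - 1`, strictly increasing.
#' @return object of class `grm_item`.
#' @export
grm_item <- function(item_id, discrimination, thresholds) {
  stopifnot(is.character(item_id), length(item_id) == 1L)
  if (!is.numeric(discrimination) || length(discrimination) != 1L ||
      !is.finite(discrimination) || discrimination <= 0)
    stop("discrimination must be a single positive number", call. = FALSE)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds) ||
      any(diff(thresholds) <= 0))
    stop("thresholds must be a strictly increasing numeric vector",
         call. = FALSE)
  structure(
    list(item_id = item_id,
         discrimination = discrimination,
         thresholds = thresholds,
         n_categories = length(thresholds) + 1L),
    class = "grm_item")
}

#' @exportS3Method base::print
print.grm_item <- function(x, ...) {
  cat(sprintf("<grm_item %s> a = %.3f, b = [%s], K = %d\n",
              x$item_id, x$discrimination,
              paste(sprintf("%.3f", x$thresholds), collapse = ", "),
              x$n_categories))
  invisible(x)
}

.as_item_bank <- function(items) {
  stopifnot(length(items) >= 1L,
            all(vapply(items, inherits, logical(1), "grm_item")))
  structure(items, class = "grm_item_bank",
            names = vapply(items, `[[`, character(1), "item_id"))
}

#' @exportS3Method base::print
print.grm_item_bank <- function(x, ...) {
  cat(sprintf("<grm_item_bank> %d items\n", length(x)))
  for (it in x) print(it)
  invisible(x)
}

#' @export
`[.grm_item_bank` <- function(x, i) .as_item_bank(unclass(x)[i])

#' Convert an item bank to a data frame (one row per item)
#'
#' Threshold columns are padded with `NA` when items differ in `K`.
#' @param x a `grm_item_bank`.
#' @param row.names,optional,... ignored.
#' @export
as.data.frame.grm_item_bank <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  kmax <- max(vapply(x, `[[`, integer(1), "n_categories"))
  th <- t(vapply(x, function(it)
    c(it$thresholds, rep(NA_real_, kmax - it$n_categories)),
    numeric(kmax - 1L)))
  out <- data.frame(
    item_id = vapply(x, `[[`, character(1), "item_id"),
    discrimination = vapply(x, `[[`, numeric(1), "discrimination"),
    n_categories = vapply(x, `[[`, integer(1), "n_categories"),
    stringsAsFactors = FALSE)
  colnames(th) <- paste0("b", seq_len(kmax - 1L))
  cbind(out, th, row.names = NULL)
}

#' Draw a random item bank with realistic graded-response parameters
#'
#' Discriminations are uniform on `[0.8, 2.5]`; thresholds are built from
#' positive gaps around a random item location, centred, and rescaled into
#' `[-2.5, 2.5]`, which keeps them strictly increasing.
#'
#' @param n_items number of items (>= 1).
#' @param n_categories number of ordered response categories `K` (>= 2),
#'   shared by all items.
#' @param seed integer seed; identical seeds give identical banks.
#' @param prefix item-id prefix.
#' @return a `grm_item_bank`.
#' @export
generate_item_bank <- function(n_items, n_categories, seed, prefix = "item") {
  if (!.is_count(n_items)) stop("n_items must be a positive integer",
                                call. = FALSE)
  if (!.is_count(n_categories) || n_categories < 2)
    stop("n_categories must be an integer >= 2", call. = FALSE)
  .with_seed(seed, {
    items <- lapply(seq_len(n_items), function(i) {
      a <- stats::runif(1, 0.8, 2.5)
      loc <- stats::runif(1, -0.75, 0.75)
      if (n_categories == 2L) {
        b <- loc
      } else {
        gaps <- stats::runif(n_categories - 2L, 0.3, 1.2)
        b <- cumsum(c(0, gaps))
        b <- b - mean(b) + loc
      }
      b <- b * min(1, 2.5 / max(abs(b)))
      grm_item(sprintf("%s%02d", prefix, i), a, b)
    })
    .as_item_bank(items)
  })
}

#' Serialize an item bank to JSON
#' @param bank a `grm_item_bank`.
#' @param path output file.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "grm_item_bank"))
  obj <- lapply(unclass(bank), function(it)
    list(item_id = it$item_id, discrimination = it$discrimination,
         thresholds = it$thresholds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an item bank from JSON
#' @param path file written by [write_item_bank()].
#' @return a `grm_item_bank`.
#' @export
read_item_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  .as_item_bank(lapply(obj, function(it)
    grm_item(it$item_id, it$discrimination, unlist(it$thresholds))))
}
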