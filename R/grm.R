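# Samejima's graded response model: category probabilities, marginal
# maximum likelihood estimation by EM, and EAP trait scoring.

.PMIN <- 1e-12

#' Quadrature settings for integrating the latent trait
#'
#' The standard-normal prior is discretised either on an equally spaced grid
#' (default: 61 nodes on `[-6, 6]` with renormalised normal weights) or by
#' Gauss-Hermite quadrature.
#'
#' @param n_nodes number of nodes (>= 11).
#' @param bounds lower/upper grid bounds (equally spaced scheme only).
#' @param scheme `"equally-spaced"` or `"gauss-hermite"`.
#' @return object of class `quadrature_config`.
#' @export
quadrature_config <- function(n_nodes = 61L, bounds = c(-6, 6),
                              scheme = c("equally-spaced", "gauss-hermite")) {
  scheme <- match.arg(scheme)
  if (!.is_count(n_nodes) || n_nodes < 11)
    stop("n_nodes must be an integer >= 11", call. = FALSE)
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("bounds must be an increasing pair", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), bounds = as.numeric(bounds),
                 scheme = scheme),
            class = "quadrature_config")
}

.quad_points <- function(quad) {
  if (quad$scheme == "gauss-hermite") {
    gh <- pracma::gaussHermite(quad$n_nodes)
    nodes <- gh$x * sqrt(2)
    w <- gh$w / sqrt(pi)
  } else {
    nodes <- seq(quad$bounds[1], quad$bounds[2], length.out = quad$n_nodes)
    w <- stats::dnorm(nodes)
  }
  list(nodes = nodes, weights = w / sum(w))
}

# K x Q matrix of category probabilities at the given nodes
.grm_prob_mat <- function(a, b, nodes) {
  K <- length(b) + 1L
  # cumulative P*(X >= k), k = 1..K-1
  pstar <- stats::plogis(a * outer(-b, nodes, `+`))  # (K-1) x Q
  up <- rbind(rep(1, length(nodes)), pstar)
  lo <- rbind(pstar, rep(0, length(nodes)))
  up - lo                                           # K x Q
}

#' Category probabilities of a graded-response item
#'
#' Cumulative boundary curves are `P*_k(theta) = logistic(a (theta - b_k))`;
#' the probability of category `k` (coded from 0) is the difference of
#' adjacent boundary curves.
#'
#' @param item a [grm_item()].
#' @param theta latent-trait value(s).
#' @return for scalar `theta` a probability vector of length `K`
#'   (sums to 1); otherwise a `length(theta) x K` matrix.
#' @export
category_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"), is.numeric(theta),
            all(is.finite(theta)))
  p <- t(.grm_prob_mat(item$discrimination, item$thresholds, theta))
  colnames(p) <- as.character(seq_len(item$n_categories) - 1L)
  if (length(theta) == 1L) drop(p) else p
}

#' Model-expected response of an item given the latent trait
#'
#' `E[X | theta] = sum_k k P_k(theta)` on the `0 ... K-1` coding; strictly
#' increasing in `theta` and bounded by `[0, K-1]`.
#'
#' @inheritParams category_probabilities
#' @return numeric vector along `theta`.
#' @export
expected_response <- function(item, theta) {
  p <- .grm_prob_mat(item$discrimination, item$thresholds, theta)
  drop(crossprod(p, seq_len(nrow(p)) - 1))[seq_along(theta)]
}

# ---- MML-EM fitting ---------------------------------------------------------

# log-likelihood matrix: n x Q, sum over observed items of log P(x | node)
.grm_loglik_mat <- function(values, bank, nodes) {
  n <- nrow(values)
  logL <- matrix(0, n, length(nodes))
  for (j in seq_along(bank)) {
    it <- bank[[j]]
    lp <- log(pmax(.grm_prob_mat(it$discrimination, it$thresholds, nodes),
                   .PMIN))
    x <- values[, j]
    obs <- which(!is.na(x))
    if (length(obs))
      logL[obs, ] <- logL[obs, ] + lp[x[obs] + 1L, , drop = FALSE]
  }
  logL
}

#' Marginal log-likelihood of a response matrix under an item bank
#'
#' Integrates the latent trait against the standard-normal prior on the
#' quadrature grid; missing responses are skipped.
#'
#' @param responses a [response_matrix()] (or integer matrix with `NA`).
#' @param bank a `grm_item_bank` whose items match the columns.
#' @param quad a [quadrature_config()].
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(responses, bank, quad = quadrature_config()) {
  stopifnot(ncol(responses) == length(bank))
  qp <- .quad_points(quad)
  lw <- log(qp$weights)
  logL <- sweep(.grm_loglik_mat(unclass(responses), bank, qp$nodes), 2, lw,
                `+`)
  m <- apply(logL, 1, max)
  sum(m + log(rowSums(exp(logL - m))))
}

.z_from_item <- function(it) {
  b <- it$thresholds
  if (length(b) == 1L) c(log(it$discrimination), b)
  else c(log(it$discrimination), b[1], log(diff(b)))
}

.b_from_z <- function(z) {
  if (length(z) == 2L) z[2] else z[2] + cumsum(c(0, exp(z[-(1:2)])))
}

# negative expected complete-data log-likelihood and gradient for one item;
# r is a K x Q matrix of expected counts
.item_obj <- function(z, r, nodes) {
  a <- exp(z[1]); b <- .b_from_z(z)
  P <- pmax(.grm_prob_mat(a, b, nodes), .PMIN)
  -sum(r * log(P))
}

.item_grad <- function(z, r, nodes) {
  a <- exp(z[1]); b <- .b_from_z(z)
  K <- length(b) + 1L
  P <- pmax(.grm_prob_mat(a, b, nodes), .PMIN)
  g <- r / P                                   # K x Q
  # P*_m enters category m (coded m-1 row m) negatively and category m+1
  # positively: dQ/dP*_m = g[m + 1] - g[m]
  D <- g[-1, , drop = FALSE] - g[-K, , drop = FALSE]  # (K-1) x Q
  pstar <- stats::plogis(a * outer(-b, nodes, `+`))
  S <- pstar * (1 - pstar)
  dQ_da <- sum(D * S * outer(-b, nodes, `+`))
  dQ_db <- -a * rowSums(D * S)                 # length K-1
  gz <- numeric(length(z))
  gz[1] <- a * dQ_da
  gz[2] <- sum(dQ_db)
  if (K > 2L)
    gz[-(1:2)] <- exp(z[-(1:2)]) * rev(cumsum(rev(dQ_db)))[-1]
  -gz
}

.init_items <- function(values, k_per_item, ids) {
  lapply(seq_len(ncol(values)), function(j) {
    x <- values[, j]
    K <- k_per_item[j]
    tab <- tabulate(x + 1L, nbins = K)
    pr <- tab / sum(tab)
    # empirical upper-tail proportions give rough threshold starts
    upper <- rev(cumsum(rev(pr)))[-1]
    b <- -stats::qlogis(.clip(upper, 0.01, 0.99))
    b <- .clip(b, -3, 3)
    for (k in seq_along(b)[-1])
      if (b[k] <= b[k - 1] + 0.05) b[k] <- b[k - 1] + 0.05
    grm_item(ids[j], 1.0, b)
  })
}

#' Fit a graded response model by marginal maximum likelihood (EM)
#'
#' E-step: posterior weights of each respondent over the quadrature nodes
#' under the standard-normal prior (which fixes the trait scale). M-step:
#' per-item BFGS maximisation of the expected complete-data log-likelihood
#' on the `(log a, b_1, log gaps)` parameterisation, which enforces a
#' positive discrimination and ordered thresholds. The marginal
#' log-likelihood is non-decreasing across iterations.
#'
#' @param responses a [response_matrix()]; missing entries are skipped in
#'   the likelihood. Every item must show at least two distinct observed
#'   categories.
#' @param quad a [quadrature_config()].
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param verbose print the likelihood trace.
#' @return object of class `grm_fit`: the fitted `bank`, final `loglik`,
#'   the per-iteration `trace`, `n_iter` and `converged`.
#' @export
fit_grm <- function(responses, quad = quadrature_config(), max_iter = 500L,
                    tol = 1e-6, verbose = FALSE) {
  values <- unclass(as.matrix(responses))
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty response matrix", call. = FALSE)
  if (all(is.na(values))) stop("all responses are missing", call. = FALSE)
  k_per_item <- if (inherits(responses, "response_matrix"))
    itemCategories(responses)
  else apply(values, 2, function(v) max(v, na.rm = TRUE) + 1L)
  ids <- colnames(values) %||% sprintf("item%02d", seq_len(ncol(values)))
  for (j in seq_len(ncol(values))) {
    nobs <- length(unique(values[!is.na(values[, j]), j]))
    if (nobs < 2L)
      stop(sprintf(
        "item '%s' has %d observed response category; at least 2 are needed",
        ids[j], nobs), call. = FALSE)
  }
  qp <- .quad_points(quad)
  lw <- log(qp$weights)
  bank <- .init_items(values, k_per_item, ids)
  obs_idx <- lapply(seq_len(ncol(values)),
                    function(j) which(!is.na(values[, j])))

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logL <- sweep(.grm_loglik_mat(values, bank, qp$nodes), 2, lw, `+`)
    m <- apply(logL, 1, max)
    post <- exp(logL - m)
    rs <- rowSums(post)
    ll <- sum(m + log(rs))
    trace <- c(trace, ll)
    if (verbose) message(sprintf("EM iter %d: logLik %.6f", iter, ll))
    if (is.finite(ll_prev) &&
        (ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    post <- post / rs
    # M-step, item by item, warm-started at the current parameters
    for (j in seq_along(bank)) {
      obs <- obs_idx[[j]]
      K <- k_per_item[j]
      r <- matrix(0, K, length(qp$nodes))
      xj <- values[obs, j]
      for (k in seq_len(K) - 1L) {
        rows <- obs[xj == k]
        if (length(rows))
          r[k + 1L, ] <- colSums(post[rows, , drop = FALSE])
      }
      z0 <- .z_from_item(bank[[j]])
      opt <- stats::optim(z0, .item_obj, .item_grad, r = r, nodes = qp$nodes,
                          method = "BFGS", control = list(maxit = 50))
      z <- if (opt$value <= .item_obj(z0, r, qp$nodes)) opt$par else z0
      bank[[j]] <- grm_item(ids[j], exp(z[1]), .b_from_z(z))
    }
  }
  structure(list(bank = .as_item_bank(bank), loglik = trace[length(trace)],
                 trace = trace, n_iter = length(trace),
                 converged = converged, quad = quad),
            class = "grm_fit")
}

#' @exportS3Method base::print
print.grm_fit <- function(x, ...) {
  cat(sprintf(
    "<grm_fit> %d items, logLik %.3f after %d EM iterations (%s)\n",
    length(x$bank), x$loglik, x$n_iter,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Expected a posteriori latent-trait scores
#'
#' Posterior mean and SD of the trait for each respondent under the
#' standard-normal prior, using observed items only. A row with no observed
#' response returns the prior itself (`theta = 0`, `posterior_sd = 1`).
#'
#' @param responses a [response_matrix()], plain integer matrix with `NA`,
#'   or a single response vector.
#' @param bank fitted or true `grm_item_bank` matching the columns.
#' @param quad a [quadrature_config()].
#' @return data frame with columns `respondent_id`, `theta`, `posterior_sd`.
#' @export
estimate_theta_eap <- function(responses, bank, quad = quadrature_config()) {
  if (is.null(dim(responses)))
    responses <- matrix(responses, nrow = 1,
                        dimnames = list("r1", names(responses)))
  values <- unclass(as.matrix(responses))
  if (ncol(values) != length(bank))
    stop(sprintf("bank has %d items but responses have %d columns",
                 length(bank), ncol(values)), call. = FALSE)
  qp <- .quad_points(quad)
  logL <- sweep(.grm_loglik_mat(values, bank, qp$nodes), 2,
                log(qp$weights), `+`)
  m <- apply(logL, 1, max)
  post <- exp(logL - m)
  post <- post / rowSums(post)
  theta <- drop(post %*% qp$nodes)
  ex2 <- drop(post %*% qp$nodes^2)
  sd <- sqrt(pmax(ex2 - theta^2, 0))
  none <- rowSums(!is.na(values)) == 0L
  theta[none] <- 0
  sd[none] <- 1
  data.frame(respondent_id = rownames(values) %||%
               sprintf("r%05d", seq_len(nrow(values))),
             theta = theta, posterior_sd = sd,
             stringsAsFactors = FALSE, row.names = NULL)
}
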