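# Classical comparators trained under the same cross-validation protocol
# as the MLP: (regularised) logistic regression, a decision tree, a
# boosted-trees learner, and a raw-response logistic baseline.

.default_grid <- function(kind) {
  switch(kind,
    logistic = expand.grid(alpha = c(0, 1),
                           lambda = c(0, 1e-3, 1e-2, 1e-1)),
    tree = expand.grid(maxdepth = c(2L, 3L, 4L, 6L),
                       cp = c(0.001, 0.01)),
    gradient_boosting = expand.grid(nrounds = c(50L, 150L),
                                    max_depth = c(2L, 3L),
                                    eta = c(0.1, 0.3)),
    stop(sprintf("unknown baseline kind '%s'", kind), call. = FALSE))
}

.fit_one_baseline <- function(kind, X, y, params, seed) {
  .with_seed(seed, switch(kind,
    logistic = glmnet::glmnet(X, y, family = "binomial",
                              alpha = params$alpha,
                              lambda = max(params$lambda, 1e-10)),
    tree = {
      df <- data.frame(y = factor(y), X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, cp = params$cp,
                     minsplit = 10, xval = 0))
    },
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0)))
}

.predict_one_baseline <- function(kind, fit, X) {
  switch(kind,
    logistic = drop(stats::predict(fit, newx = X, type = "response")),
    tree = stats::predict(fit, newdata = data.frame(X),
                          type = "prob")[, "1"],
    gradient_boosting = stats::predict(
      fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Train a baseline classifier with grid search under cross-validation
#'
#' Every grid point is scored by mean validation AUC over the CV repeats
#' (same fold layout as [train_mlp()]); the best point is refit on the full
#' training data. Supported kinds: `"logistic"` (elastic-net logistic
#' regression), `"tree"` (CART decision tree) and `"gradient_boosting"`
#' (histogram boosted trees).
#'
#' @param kind baseline family.
#' @param features numeric feature table (no missing values).
#' @param labels binary 0/1 outcome.
#' @param grid data frame of hyperparameter combinations (defaults per
#'   kind); must be non-empty.
#' @param cv a [cv_config()].
#' @param seed master seed.
#' @return object of class `lqr_model`.
#' @export
train_baseline <- function(kind = c("logistic", "tree",
                                    "gradient_boosting"),
                           features, labels, grid = NULL,
                           cv = cv_config(), seed = 1L) {
  kind <- match.arg(kind)
  X <- .check_features(features)
  y <- .check_labels(labels)
  if (is.null(grid)) grid <- .default_grid(kind)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  fold <- .make_folds(y, cv$n_folds, derive_seeds(seed, 1L))
  fit_seeds <- derive_seeds(seed + 1L, cv$n_folds + 1L)
  grid_auc <- numeric(nrow(grid))
  val_scores <- matrix(NA_real_, length(y), nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(cv$n_folds)
    vs <- numeric(length(y)); vc <- integer(length(y))
    for (j in seq_len(cv$n_folds)) {
      val <- fold %in% .val_folds(j, cv)
      fit <- .fit_one_baseline(kind, X[!val, , drop = FALSE], y[!val],
                               grid[g, , drop = FALSE], fit_seeds[j])
      pv <- .predict_one_baseline(kind, fit, X[val, , drop = FALSE])
      aucs[j] <- auc(pv, y[val])
      vs[val] <- vs[val] + pv; vc[val] <- vc[val] + 1L
    }
    grid_auc[g] <- mean(aucs)
    val_scores[, g] <- vs / pmax(vc, 1L)
  }
  g_best <- which.max(grid_auc)  # ties: first point in grid order
  fit <- .fit_one_baseline(kind, X, y, grid[g_best, , drop = FALSE],
                           fit_seeds[cv$n_folds + 1L])
  structure(list(kind = kind, fit = fit,
                 params = as.list(grid[g_best, , drop = FALSE]),
                 grid = grid, grid_auc = grid_auc,
                 feature_names = colnames(X),
                 validation_scores = val_scores[, g_best],
                 train_prevalence = mean(y), seed = seed),
            class = "lqr_model")
}

#' Logistic baseline on raw questionnaire responses
#'
#' Plain logistic regression using the (imputed) raw item category codes as
#' predictors, evaluated under the same cross-validation protocol — the
#' reference the low-quality-response features are compared against.
#'
#' @param responses imputed [response_matrix()] (no missing entries).
#' @param labels binary 0/1 outcome.
#' @param cv a [cv_config()].
#' @param seed master seed.
#' @return object of class `lqr_model` (kind `"raw_response_logistic"`).
#' @export
train_raw_response_baseline <- function(responses, labels,
                                        cv = cv_config(), seed = 1L) {
  X <- .check_features(unclass(as.matrix(responses)))
  y <- .check_labels(labels)
  fold <- .make_folds(y, cv$n_folds, derive_seeds(seed, 1L))
  vs <- numeric(length(y)); vc <- integer(length(y))
  aucs <- numeric(cv$n_folds)
  for (j in seq_len(cv$n_folds)) {
    val <- fold %in% .val_folds(j, cv)
    df <- data.frame(y = y[!val], X[!val, , drop = FALSE])
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    pv <- stats::predict(fit, newdata = data.frame(X[val, , drop = FALSE]),
                         type = "response")
    aucs[j] <- auc(pv, y[val])
    vs[val] <- vs[val] + pv; vc[val] <- vc[val] + 1L
  }
  fit <- stats::glm(y ~ ., data = data.frame(y = y, X),
                    family = stats::binomial())
  structure(list(kind = "raw_response_logistic", fit = fit,
                 fold_val_auc = aucs, feature_names = colnames(X),
                 validation_scores = vs / pmax(vc, 1L),
                 train_prevalence = mean(y), seed = seed),
            class = "lqr_model")
}

#' Predict cognitive-impairment risk scores
#'
#' Applies a trained model to a feature table whose columns must match the
#' training layout. Scores are probabilities in `[0, 1]`, computed row-wise
#' and deterministically.
#'
#' @param model an `lqr_model` from [train_mlp()], [train_baseline()] or
#'   [train_raw_response_baseline()].
#' @param features feature table (raw responses for the raw-response
#'   baseline).
#' @return numeric vector of risk scores.
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "lqr_model"))
  X <- .check_features(if (inherits(features, "response_matrix"))
    unclass(as.matrix(features)) else features)
  if (!identical(colnames(X), model$feature_names))
    stop(sprintf(
      "feature layout mismatch: model expects [%s], received [%s]",
      paste(model$feature_names, collapse = ", "),
      paste(colnames(X), collapse = ", ")), call. = FALSE)
  switch(model$kind,
    mlp = .mlp_forward(model$net, X)$p,
    raw_response_logistic = unname(stats::predict(
      model$fit, newdata = data.frame(X), type = "response")),
    .predict_one_baseline(model$kind, model$fit, X))
}

#' @exportS3Method base::print
print.lqr_model <- function(x, ...) {
  cat(sprintf("<lqr_model> kind = %s, %d features, train prevalence %.3f\n",
              x$kind, length(x$feature_names), x$train_prevalence))
  if (x$kind == "mlp")
    cat(sprintf("  selected CV repeat %d (val AUC %.3f, best epoch %d)\n",
                x$selected_fold, max(x$fold_val_auc), x$best_epoch))
  invisible(x)
}

#' Serialize / restore a trained model
#'
#' Models round-trip bit-identically: predictions from a restored model
#' equal those of the original exactly.
#'
#' @param model an `lqr_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lqr_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lqr_model"))
  model
}
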