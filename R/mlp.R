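# A small dense feed-forward classifier trained with Adam: four hidden
# ReLU layers with batch normalization and dropout, a sigmoid output with
# prevalence-based bias initialisation, class-weighted binary
# cross-entropy, reduce-on-plateau learning rate and early stopping
# monitored on validation AUC.

#' Multilayer-perceptron configuration
#'
#' @param hidden_layers widths of the hidden layers (default four layers:
#'   64, 32, 16, 8).
#' @param dropout_rates dropout probability after each hidden layer, in
#'   `[0, 1)`.
#' @param batch_norm apply batch normalization before each ReLU (supports
#'   raw, unscaled feature input).
#' @param learning_rate initial Adam learning rate.
#' @param lr_factor,lr_patience reduce-on-plateau schedule: multiply the
#'   learning rate by `lr_factor` after `lr_patience` epochs without
#'   validation-AUC improvement.
#' @param early_stopping_patience epochs without validation-AUC improvement
#'   before stopping; the best-epoch weights are restored.
#' @param max_epochs,batch_size training budget.
#' @param class_weighting weight class `c` by `n / (2 n_c)`.
#' @return object of class `mlp_config`.
#' @export
mlp_config <- function(hidden_layers = c(64L, 32L, 16L, 8L),
                       dropout_rates = rep(0.2, length(hidden_layers)),
                       batch_norm = TRUE,
                       learning_rate = 1e-3,
                       lr_factor = 0.5, lr_patience = 3L,
                       early_stopping_patience = 10L,
                       max_epochs = 200L, batch_size = 256L,
                       class_weighting = TRUE) {
  stopifnot(length(hidden_layers) >= 1L, all(hidden_layers >= 1),
            length(dropout_rates) == length(hidden_layers),
            all(dropout_rates >= 0 & dropout_rates < 1),
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropout_rates = dropout_rates,
                 batch_norm = isTRUE(batch_norm),
                 learning_rate = learning_rate,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 class_weighting = isTRUE(class_weighting)),
            class = "mlp_config")
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.mlp_init <- function(d_in, cfg, output_bias) {
  widths <- c(d_in, cfg$hidden_layers)
  layers <- lapply(seq_along(cfg$hidden_layers), function(l) {
    fan_in <- widths[l]
    list(W = matrix(stats::rnorm(fan_in * widths[l + 1L],
                                 sd = sqrt(2 / fan_in)),
                    fan_in, widths[l + 1L]),
         b = rep(0, widths[l + 1L]),
         gamma = rep(1, widths[l + 1L]),
         beta = rep(0, widths[l + 1L]),
         run_mean = rep(0, widths[l + 1L]),
         run_var = rep(1, widths[l + 1L]))
  })
  d_last <- widths[length(widths)]
  list(layers = layers,
       out = list(W = matrix(stats::rnorm(d_last, sd = sqrt(2 / d_last)),
                             d_last, 1),
                  b = output_bias),
       cfg = cfg)
}

# forward pass; train = TRUE uses batch statistics and dropout masks
.mlp_forward <- function(net, X, train = FALSE, masks = NULL) {
  cfg <- net$cfg
  caches <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, `+`)
    if (cfg$batch_norm) {
      if (train) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv <- 1 / sqrt(v + .BN_EPS)
      xhat <- sweep(sweep(Z, 2, mu), 2, inv, `*`)
      Zn <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    } else {
      mu <- NULL; v <- NULL; inv <- NULL; xhat <- NULL; Zn <- Z
    }
    H <- pmax(Zn, 0)
    if (train && cfg$dropout_rates[l] > 0) {
      p <- cfg$dropout_rates[l]
      mask <- if (!is.null(masks)) masks[[l]] else
        matrix(stats::rbinom(length(H), 1, 1 - p) / (1 - p),
               nrow(H), ncol(H))
      Hd <- H * mask
    } else {
      mask <- NULL; Hd <- H
    }
    caches[[l]] <- list(A = A, Z = Z, mu = mu, v = v, inv = inv,
                        xhat = xhat, Zn = Zn, mask = mask)
    A <- Hd
  }
  z <- drop(A %*% net$out$W) + net$out$b
  list(p = stats::plogis(z), z = z, A_last = A, caches = caches)
}

# weighted binary cross-entropy: mean over the batch of w_i * bce_i
.mlp_loss <- function(p, y, w) {
  p <- .clip(p, 1e-12, 1 - 1e-12)
  mean(w * -(y * log(p) + (1 - y) * log(1 - p)))
}

# gradients of the weighted BCE w.r.t. all parameters
.mlp_backward <- function(net, fwd, X, y, w) {
  cfg <- net$cfg
  m <- length(y)
  dz <- matrix(w * (fwd$p - y) / m, ncol = 1)
  g_out <- list(W = crossprod(fwd$A_last, dz), b = sum(dz))
  dA <- dz %*% t(net$out$W)
  g_layers <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    ca <- net$layers[[l]]
    cache <- fwd$caches[[l]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZn <- dA * (cache$Zn > 0)
    if (cfg$batch_norm) {
      mb <- nrow(dZn)
      dgamma <- colSums(dZn * cache$xhat)
      dbeta <- colSums(dZn)
      dxhat <- sweep(dZn, 2, ca$gamma, `*`)
      zc <- sweep(cache$Z, 2, cache$mu)
      dvar <- colSums(dxhat * zc) * (-0.5) * cache$inv^3
      dmu <- colSums(dxhat) * (-cache$inv) +
        dvar * (-2) * colMeans(zc)
      dZ <- sweep(dxhat, 2, cache$inv, `*`) +
        sweep(zc, 2, 2 * dvar / mb, `*`) +
        matrix(dmu / mb, mb, length(dmu), byrow = TRUE)
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- dZn
    }
    g_layers[[l]] <- list(W = crossprod(cache$A, dZ), b = colSums(dZ),
                          gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(ca$W)
  }
  list(layers = g_layers, out = g_out)
}

.adam_state <- function(net) {
  zero_like <- function(x) if (is.null(x)) NULL else x * 0
  list(t = 0,
       layers = lapply(net$layers, function(ly)
         list(m = lapply(ly[c("W", "b", "gamma", "beta")], zero_like),
              v = lapply(ly[c("W", "b", "gamma", "beta")], zero_like))),
       out = list(m = lapply(net$out[c("W", "b")], zero_like),
                  v = lapply(net$out[c("W", "b")], zero_like)))
}

.adam_update <- function(par, grad, m, v, lr, t,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.mlp_step <- function(net, state, grads, lr) {
  state$t <- state$t + 1
  t <- state$t
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", if (net$cfg$batch_norm) c("gamma", "beta"))) {
      up <- .adam_update(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
                         state$layers[[l]]$m[[nm]],
                         state$layers[[l]]$v[[nm]], lr, t)
      net$layers[[l]][[nm]] <- up$par
      state$layers[[l]]$m[[nm]] <- up$m
      state$layers[[l]]$v[[nm]] <- up$v
    }
  }
  for (nm in c("W", "b")) {
    up <- .adam_update(net$out[[nm]], grads$out[[nm]],
                       state$out$m[[nm]], state$out$v[[nm]], lr, t)
    net$out[[nm]] <- up$par
    state$out$m[[nm]] <- up$m
    state$out$v[[nm]] <- up$v
  }
  list(net = net, state = state)
}

# update running batch-norm statistics after a training batch
.mlp_update_running <- function(net, fwd) {
  if (!net$cfg$batch_norm) return(net)
  for (l in seq_along(net$layers)) {
    cache <- fwd$caches[[l]]
    net$layers[[l]]$run_mean <- .BN_MOMENTUM * net$layers[[l]]$run_mean +
      (1 - .BN_MOMENTUM) * cache$mu
    net$layers[[l]]$run_var <- .BN_MOMENTUM * net$layers[[l]]$run_var +
      (1 - .BN_MOMENTUM) * cache$v
  }
  net
}

# train one network on (X, y) with early stopping on (Xv, yv) AUC
.mlp_train_one <- function(X, y, Xv, yv, cfg, seed) {
  .with_seed(seed, {
    prev <- mean(y)
    w1 <- if (cfg$class_weighting)
      length(y) / (2 * sum(y == 1)) else 1
    w0 <- if (cfg$class_weighting)
      length(y) / (2 * sum(y == 0)) else 1
    w <- ifelse(y == 1, w1, w0)
    net <- .mlp_init(ncol(X), cfg, stats::qlogis(.clip(prev, 1e-6,
                                                       1 - 1e-6)))
    state <- .adam_state(net)
    lr <- cfg$learning_rate
    best_auc <- -Inf; best_net <- net
    best_epoch <- 0L; stale <- 0L; stale_lr <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_auc = numeric(0), lr = numeric(0))
    n <- nrow(X)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch statistics need >= 2 rows
        fwd <- .mlp_forward(net, X[idx, , drop = FALSE], train = TRUE)
        losses <- c(losses, .mlp_loss(fwd$p, y[idx], w[idx]))
        grads <- .mlp_backward(net, fwd, X[idx, , drop = FALSE],
                               y[idx], w[idx])
        upd <- .mlp_step(net, state, grads, lr)
        net <- .mlp_update_running(upd$net, fwd)
        state <- upd$state
      }
      val_auc <- auc(.mlp_forward(net, Xv)$p, yv)
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = mean(losses),
                                  val_auc = val_auc, lr = lr))
      if (val_auc > best_auc + 1e-9) {
        best_auc <- val_auc; best_net <- net; best_epoch <- epoch
        stale <- 0L; stale_lr <- 0L
      } else {
        stale <- stale + 1L; stale_lr <- stale_lr + 1L
        if (stale_lr >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          stale_lr <- 0L
        }
        if (stale >= cfg$early_stopping_patience) break
      }
    }
    list(net = best_net, val_auc = best_auc, best_epoch = best_epoch,
         history = history)
  })
}

#' Train the class-weighted multilayer perceptron under cross-validation
#'
#' The training set is partitioned into folds; each CV repeat trains on
#' 80\% with early stopping monitored on the remaining 20\% validation
#' subset (see [cv_config()]). Only the repeat with the highest validation
#' AUC is retained. Validation predictions pooled across repeats (each row
#' is scored whenever it falls in a validation subset) are stored for
#' leakage-free threshold selection.
#'
#' @param features numeric feature table (no missing values).
#' @param labels binary 0/1 outcome.
#' @param cfg an [mlp_config()].
#' @param cv a [cv_config()].
#' @param seed master seed; per-repeat seeds are derived from it.
#' @return object of class `lqr_model` (kind `"mlp"`).
#' @export
train_mlp <- function(features, labels, cfg = mlp_config(),
                      cv = cv_config(), seed = 1L) {
  X <- .check_features(features)
  y <- .check_labels(labels)
  stopifnot(nrow(X) == length(y))
  fold <- .make_folds(y, cv$n_folds, derive_seeds(seed, 1L))
  fold_seeds <- derive_seeds(seed + 1L, cv$n_folds)
  val_sum <- numeric(length(y)); val_cnt <- integer(length(y))
  fold_auc <- numeric(cv$n_folds)
  best <- NULL
  for (j in seq_len(cv$n_folds)) {
    vf <- .val_folds(j, cv)
    val <- fold %in% vf
    res <- .mlp_train_one(X[!val, , drop = FALSE], y[!val],
                          X[val, , drop = FALSE], y[val],
                          cfg, fold_seeds[j])
    fold_auc[j] <- res$val_auc
    pv <- .mlp_forward(res$net, X[val, , drop = FALSE])$p
    val_sum[val] <- val_sum[val] + pv
    val_cnt[val] <- val_cnt[val] + 1L
    if (is.null(best) || res$val_auc > best$val_auc) {
      best <- res
      best$fold <- j
    }
  }
  structure(list(kind = "mlp", net = best$net, cfg = cfg, cv = cv,
                 feature_names = colnames(X),
                 fold_val_auc = fold_auc, selected_fold = best$fold,
                 best_epoch = best$best_epoch, history = best$history,
                 validation_scores = val_sum / pmax(val_cnt, 1L),
                 train_prevalence = mean(y), seed = seed),
            class = "lqr_model")
}
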