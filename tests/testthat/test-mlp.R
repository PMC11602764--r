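# two gaussian clouds with a mean offset: linearly separable up to noise
make_gaussians <- function(n, d = 12, delta = 1.2, p_pos = 0.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, p_pos)
    X <- matrix(rnorm(n * d), n, d) + outer(y, rep(delta, d))
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y)
  })
}

test_that("network gradients match finite differences", {
  withr::with_seed(3, {
    cfg <- mlp_config(hidden_layers = c(5L, 4L), dropout_rates = c(0, 0),
                      batch_norm = TRUE)
    X <- matrix(rnorm(8 * 3), 8, 3)
    y <- rbinom(8, 1, 0.5)
    w <- runif(8, 0.5, 2)
    net <- lqrscreen:::.mlp_init(3, cfg, output_bias = -0.4)
    fwd <- lqrscreen:::.mlp_forward(net, X, train = TRUE)
    grads <- lqrscreen:::.mlp_backward(net, fwd, X, y, w)
    loss_at <- function(net) {
      f <- lqrscreen:::.mlp_forward(net, X, train = TRUE)
      lqrscreen:::.mlp_loss(f$p, y, w)
    }
    eps <- 1e-6
    check <- function(get, set, g) {
      par <- get(net)
      idx <- seq_len(min(length(par), 6L))
      for (i in idx) {
        np <- par; np[i] <- np[i] + eps
        up <- set(net, np)
        num <- (loss_at(up) - loss_at(net)) / eps
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
    check(function(n) n$layers[[1]]$W,
          function(n, p) { n$layers[[1]]$W[] <- p; n },
          grads$layers[[1]]$W)
    check(function(n) n$layers[[2]]$gamma,
          function(n, p) { n$layers[[2]]$gamma <- p; n },
          grads$layers[[2]]$gamma)
    check(function(n) n$layers[[2]]$beta,
          function(n, p) { n$layers[[2]]$beta <- p; n },
          grads$layers[[2]]$beta)
    check(function(n) n$out$W,
          function(n, p) { n$out$W[] <- p; n },
          grads$out$W)
  })
})

test_that("the MLP separates linearly separable classes", {
  dat <- make_gaussians(2000, seed = 11)
  tr <- seq_len(1400); te <- 1401:2000
  model <- train_mlp(dat$X[tr, ], dat$y[tr],
                     mlp_config(max_epochs = 60), cv_config(5), seed = 12)
  scores <- predict_risk(model, dat$X[te, ])
  expect_true(all(scores >= 0 & scores <= 1))
  expect_gte(auc(scores, dat$y[te]), 0.95)
  # early stopping keeps the best epoch on record
  expect_gte(model$history$val_auc[model$best_epoch],
             model$history$val_auc[nrow(model$history)])
})

test_that("degenerate inputs are rejected with useful errors", {
  dat <- make_gaussians(60, seed = 13)
  expect_error(train_mlp(dat$X, rep(1, 60)), "single class")
  Xna <- dat$X; Xna[1, 1] <- NA
  expect_error(train_mlp(Xna, dat$y), "impute")
})

test_that("class weighting protects sensitivity under imbalance", {
  wins <- vapply(1:8, function(s) {
    dat <- make_gaussians(900, d = 6, delta = 0.9, p_pos = 0.1,
                          seed = 20 + s)
    tr <- seq_len(600); te <- 601:900
    cfgw <- mlp_config(hidden_layers = c(16L, 8L), dropout_rates = c(0, 0),
                       max_epochs = 40, class_weighting = TRUE)
    cfgu <- mlp_config(hidden_layers = c(16L, 8L), dropout_rates = c(0, 0),
                       max_epochs = 40, class_weighting = FALSE)
    mw <- train_mlp(dat$X[tr, ], dat$y[tr], cfgw, cv_config(3),
                    seed = 30 + s)
    mu <- train_mlp(dat$X[tr, ], dat$y[tr], cfgu, cv_config(3),
                    seed = 30 + s)
    sens <- function(m) {
      p <- predict_risk(m, dat$X[te, ])
      mean(p[dat$y[te] == 1] > 0.5)
    }
    sens(mw) - sens(mu)
  }, numeric(1))
  expect_gte(mean(wins), 0)
})

test_that("predictions are pure, deterministic and serializable", {
  dat <- make_gaussians(600, seed = 41)
  model <- train_mlp(dat$X[1:400, ], dat$y[1:400],
                     mlp_config(max_epochs = 20), cv_config(3), seed = 42)
  p1 <- predict_risk(model, dat$X[401:600, ])
  p2 <- predict_risk(model, dat$X[401:600, ])
  expect_identical(p1, p2)
  # duplicating a row duplicates its score
  Xdup <- dat$X[c(401, 401, 402), ]
  pd <- predict_risk(model, Xdup)
  expect_identical(pd[1], pd[2])
  # round-trip through disk is bit-identical
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(predict_risk(load_model(path), dat$X[401:600, ]), p1)
  # layout mismatches are explained
  Xbad <- dat$X[401:600, ]; colnames(Xbad)[1] <- "zz"
  expect_error(predict_risk(model, Xbad), "layout mismatch")
})
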