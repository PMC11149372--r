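# logistic-regression and neural-network predictors

test_that("ridge logistic matches a brute-force objective minimization", {
  set.seed(1)
  n <- 400
  X <- matrix(rnorm(3 * n), n, 3)
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0.2)))
  l2 <- 2
  fit <- train_lr(X, y, l2_strength = l2)
  oracle <- optim(rep(0, 4), ridge_logistic_objective, X = X, y = y, l2 = l2,
                  method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(c(fit$intercept, fit$beta) - oracle$par)), 1e-4)
  obj_fit <- ridge_logistic_objective(c(fit$intercept, fit$beta), X, y, l2)
  expect_lt(obj_fit - oracle$value, 1e-6)
})

test_that("LR separates separable data and is null on noise", {
  xy <- separable_xy(200, seed = 2)
  fit <- train_lr(xy$X, xy$y)
  expect_equal(auroc(predict(fit, xy$X), xy$y), 1)
  set.seed(3)
  Xn <- matrix(rnorm(2000 * 5), 2000, 5)
  yn <- rbinom(2000, 1, 0.5)
  fit_n <- train_lr(Xn[1:1000, ], yn[1:1000])
  expect_lt(abs(auroc(predict(fit_n, Xn[1001:2000, ]), yn[1001:2000]) - 0.5),
            0.05)
  expect_error(train_lr(Xn, rep(0, 2000)), "one class")
})

test_that("the network learns a nonlinear rule that defeats LR", {
  set.seed(4)
  n <- 2000
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- as.integer(X[, 1] * X[, 2] > 0)         # XOR-style parity
  tr <- 1:1600; va <- 1601:1800; te <- 1801:2000
  dn <- train_dnn(X[tr, ], y[tr], X[va, ], y[va], dnn_config(seed = 7))
  expect_gt(auroc(predict(dn, X[tr, ]), y[tr]), 0.95)
  expect_gt(auroc(predict(dn, X[te, ]), y[te]), 0.95)
  lr <- train_lr(X[tr, ], y[tr])
  expect_lt(auroc(predict(lr, X[te, ]), y[te]), 0.6)
})

test_that("training is seed-deterministic and loss decreases", {
  xy <- separable_xy(300, seed = 5)
  cfg <- dnn_config(seed = 11, max_epochs = 50)
  f1 <- train_dnn(xy$X[1:200, ], xy$y[1:200], xy$X[201:300, ], xy$y[201:300],
                  cfg)
  f2 <- train_dnn(xy$X[1:200, ], xy$y[1:200], xy$X[201:300, ], xy$y[201:300],
                  cfg)
  expect_identical(f1$weights, f2$weights)
  expect_lt(f1$history$train_loss[nrow(f1$history)],
            f1$history$train_loss[1])
})

test_that("a large L1 penalty shrinks predictions to the base rate", {
  xy <- separable_xy(200, seed = 6)
  dn <- train_dnn(xy$X[1:150, ], xy$y[1:150], xy$X[151:200, ], xy$y[151:200],
                  dnn_config(seed = 1, lambda1 = 50, max_epochs = 50,
                             dropout = 0))
  p <- predict(dn, xy$X)
  expect_lt(sd(p), 0.05)
  expect_lt(abs(mean(p) - mean(xy$y[1:150])), 0.15)
})

test_that("the degenerate network reproduces ridge logistic regression", {
  # hidden layer removed, no dropout, matched L2: a logistic unit under SGD
  # should converge to the penalized-likelihood optimum of train_lr
  set.seed(7)
  n <- 300
  X <- matrix(rnorm(2 * n), n, 2)
  y <- rbinom(n, 1, plogis(X %*% c(1.2, -0.8)))
  tr <- 1:200; va <- 201:300
  l2 <- 2
  dn <- train_dnn(X[tr, ], y[tr], X[va, ], y[va],
                  dnn_config(hidden_nodes = 0, dropout = 0, lambda1 = 0,
                             lambda2 = l2 / (2 * length(tr)),
                             max_epochs = 500, patience = 500,
                             learning_rate = 0.25, lr_decay = 0.001,
                             clipnorm = 0, standardize = FALSE, seed = 2))
  lr <- train_lr(X[tr, ], y[tr], l2_strength = l2)
  p_dn <- predict(dn, X[va, ])
  p_lr <- predict(lr, X[va, ])
  expect_gt(cor(p_dn, p_lr), 0.99)
  expect_lt(mean(abs(p_dn - p_lr)), 0.05)
})

test_that("prediction is consistent, bounded and monotone for LR", {
  xy <- separable_xy(50, seed = 8)
  fit <- train_lr(xy$X, xy$y)
  p <- predict(fit, xy$X)
  expect_true(all(p > 0 & p < 1))
  # batch equals per-row
  p_rows <- vapply(seq_len(nrow(xy$X)), function(i)
    predict(fit, xy$X[i, , drop = FALSE]), numeric(1))
  expect_equal(p, p_rows)
  # increasing a positively weighted feature never decreases the output
  j <- which.max(fit$beta)
  X_up <- xy$X; X_up[, j] <- X_up[, j] + 1
  expect_true(all(predict(fit, X_up) >= p))
  expect_error(predict(fit, xy$X[, 1, drop = FALSE]), "feature count")
  # zero-weight model outputs exactly 1/2
  fit0 <- fit; fit0$beta[] <- 0; fit0$intercept <- 0
  expect_true(all(predict(fit0, xy$X) == 0.5))
})
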