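# transfer learning: fine-tuning behavior and the linear transfer model

test_that("zero fine-tuning epochs return the pretrained model exactly", {
  xy <- separable_xy(300, seed = 1)
  tr <- 1:200; va <- 201:300
  src <- train_dnn(xy$X[tr, ], xy$y[tr], xy$X[va, ], xy$y[va],
                   dnn_config(seed = 3, max_epochs = 20))
  cfg0 <- src$config; cfg0$max_epochs <- 0L
  ft <- fine_tune_dnn(src, xy$X[tr, ], xy$y[tr], xy$X[va, ], xy$y[va],
                      config = cfg0)
  expect_equal(ft$weights, src$weights)
  expect_equal(predict(ft, xy$X), predict(src, xy$X))
})

test_that("fine-tuning never mutates the pretrained model", {
  xy <- separable_xy(300, seed = 2)
  tr <- 1:200; va <- 201:300
  src <- train_dnn(xy$X[tr, ], xy$y[tr], xy$X[va, ], xy$y[va],
                   dnn_config(seed = 4, max_epochs = 20))
  before <- serialize(src, NULL)
  p_before <- predict(src, xy$X)
  ft <- fine_tune_dnn(src, xy$X[tr, ], 1 - xy$y[tr], xy$X[va, ],
                      1 - xy$y[va])
  expect_identical(serialize(src, NULL), before)
  expect_identical(predict(src, xy$X), p_before)
  expect_false(identical(ft$weights, src$weights))
})

test_that("fine-tuning on the source domain preserves performance", {
  set.seed(5)
  n <- 900
  X <- matrix(rnorm(6 * n), n, 6)
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5, 0, 0, 0)))
  tr <- 1:600; va <- 601:750; te <- 751:900
  src <- train_dnn(X[tr, ], y[tr], X[va, ], y[va], dnn_config(seed = 6))
  ft <- fine_tune_dnn(src, X[tr, ], y[tr], X[va, ], y[va])
  a_src <- auroc(predict(src, X[te, ]), y[te])
  a_ft <- auroc(predict(ft, X[te, ]), y[te])
  expect_lt(abs(a_src - a_ft), 0.05)
})

test_that("linear transfer collapses to naive transfer under a huge penalty", {
  set.seed(7)
  X <- matrix(rnorm(5 * 300), 300, 5)
  y <- rbinom(300, 1, plogis(X %*% c(1, -0.5, 0, 0.3, 0)))
  src <- train_lr(X[1:150, ], y[1:150])
  tl <- fit_linear_transfer(src, X[151:300, ], y[151:300], penalty = 1e9)
  expect_lt(max(abs(tl$tau)), 1e-4)
  # feature effects collapse to the source model (the intercept stays free,
  # so scores agree up to that recalibration: identical ranking)
  expect_equal(tl$beta, src$beta, tolerance = 1e-6)
  expect_equal(auroc(predict(tl, X), y), auroc(predict(src, X), y))
})

test_that("zero-pretraining, near-zero-penalty transfer equals a direct fit", {
  set.seed(8)
  X <- matrix(rnorm(4 * 400), 400, 4)
  y <- rbinom(400, 1, plogis(X %*% c(0.8, -0.8, 0.4, 0)))
  null_src <- list(intercept = 0, beta = rep(0, 4))
  tl <- fit_linear_transfer(null_src, X, y, penalty = 1e-6)
  direct <- train_lr(X, y, l2_strength = 1e-6)
  expect_lt(max(abs(tl$beta - direct$beta)), 1e-3)
})

test_that("with matched source and target the adjustments are small", {
  # parameter-recovery: when the source model is fit on a large sample of the
  # same distribution, tau should hover near zero
  set.seed(9)
  beta_true <- c(1, -0.7, 0.4)
  X_src <- matrix(rnorm(3 * 4000), 4000, 3)
  y_src <- rbinom(4000, 1, plogis(X_src %*% beta_true))
  src <- train_lr(X_src, y_src)
  X_tgt <- matrix(rnorm(3 * 1000), 1000, 3)
  y_tgt <- rbinom(1000, 1, plogis(X_tgt %*% beta_true))
  tl <- fit_linear_transfer(src, X_tgt, y_tgt, penalty = 1)
  # each adjustment within ~2 SE of an unpenalized logistic coefficient
  se <- sqrt(diag(vcov(glm(y_tgt ~ X_tgt, family = binomial()))))[-1]
  expect_true(all(abs(tl$tau) < 2.5 * se))
})

test_that("shifted target effects pull the fitted betas toward the truth", {
  set.seed(10)
  m <- 30
  W <- draw_effects(m, seed = 1)
  Wp <- correlate_effects(W, 0.5, seed = 2)
  X_src <- matrix(rbinom(4000 * m, 2, 0.4), 4000, m)
  y_src <- rbinom(4000, 1, plogis(scale(X_src %*% W)))
  X_tgt <- matrix(rbinom(1500 * m, 2, 0.4), 1500, m)
  y_tgt <- rbinom(1500, 1, plogis(scale(X_tgt %*% Wp)))
  src <- train_lr(X_src, y_src)
  tl <- fit_linear_transfer(src, X_tgt[1:1200, ], y_tgt[1:1200],
                            X_val = X_tgt[1301:1500, ],
                            y_val = y_tgt[1301:1500])
  # scale-free comparison: correlation with the true shifted effects
  expect_gt(cor(tl$beta, Wp), cor(src$beta, Wp))
})
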