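# shared fixtures: built in code, small enough to keep every file fast

tiny_dataset <- function(seed = 1) make_fixture("tiny", seed = seed)

# a linearly separable two-feature problem
separable_xy <- function(n = 100, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n), n, 2)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
  list(X = X, y = y)
}

# brute-force penalized ridge-logistic objective (oracle for train_lr)
ridge_logistic_objective <- function(par, X, y, l2) {
  eta <- par[1] + X %*% par[-1]
  -sum(y * eta - log1p(exp(eta))) + l2 / 2 * sum(par[-1]^2)
}
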