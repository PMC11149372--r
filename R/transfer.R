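# Transfer learning EUR -> DDP: supervised fine-tuning of the neural network,
# and the linear transfer model in which target effects decompose as
# pretrained effects plus penalized adjustments.

#' Fine-tune a pretrained neural network on target-domain data
#'
#' Continues SGD training from the pretrained weights using the target
#' domain's training data, with the same optimizer configuration as
#' pretraining (all layers trainable); early stopping and best-weight
#' restoration monitor the target validation split. The pretrained model
#' object is never modified -- the source-population model is unaffected by
#' any transfer run.
#'
#' @param pretrained A fitted `eqg_dnn` (source domain).
#' @param X_train,y_train,X_val,y_val Target-domain splits (same feature
#'   schema as the source).
#' @param config Optional [dnn_config()] override; defaults to the
#'   pretraining config with a fresh seed derived from it.
#' @return A new fitted `eqg_dnn` (the transferred model).
#' @export
fine_tune_dnn <- function(pretrained, X_train, y_train, X_val, y_val,
                          config = NULL) {
  stopifnot(inherits(pretrained, "eqg_dnn"))
  if (ncol(X_train) != pretrained$n_features)
    stop("target features do not match the pretrained schema")
  if (is.null(config)) {
    config <- pretrained$config
    if (is.null(config)) stop("pretrained model carries no config; supply one")
    config$seed <- derive_seed(config$seed, "fine-tune")
  }
  # target data enter on the source model's feature scale
  X_train <- scale_features(X_train, pretrained$scaling)
  X_val <- scale_features(X_val, pretrained$scaling)
  res <- dnn_train_cpp(X_train, as.numeric(y_train), X_val, as.numeric(y_val),
                       pretrained$hidden, config$dropout,
                       config$learning_rate, config$lr_decay, config$momentum,
                       config$lambda1, config$lambda2, config$batch_size,
                       config$max_epochs, config$patience, config$seed,
                       config$clipnorm %||% 0,
                       as.integer(pretrained$n_updates %||% 0),
                       pretrained$weights)
  structure(list(kind = "DL", hidden = pretrained$hidden,
                 weights = res$weights, history = res$history,
                 best_epoch = res$best_epoch,
                 best_val_accuracy = res$best_val_accuracy,
                 stopped_epoch = res$stopped_epoch,
                 n_updates = (pretrained$n_updates %||% 0) + res$n_updates,
                 n_features = pretrained$n_features,
                 scaling = pretrained$scaling,
                 feature_names = pretrained$feature_names, config = config,
                 fine_tuned = TRUE,
                 # identity echo of the source model and target data
                 source_fingerprint = sum(abs(unlist(pretrained$weights))),
                 target_n = nrow(X_train)),
            class = c("eqg_dnn", "eqg_model"))
}

#' Fit the linear transfer model on target-domain data
#'
#' The target-population effect of each feature decomposes as the pretrained
#' (source) effect plus an adjustment: `beta_j = beta_j_pre + tau_j` for SNPs
#' and `gamma_k = gamma_k_pre + delta_k` for clinical covariates. The
#' adjustments are estimated by L2-penalized logistic regression on the
#' target training data with the pretrained linear predictor supplied as a
#' fixed offset, so the penalty shrinks the target model toward the source
#' model: `penalty -> Inf` recovers naive transfer, `penalty -> 0` a free
#' target refit. When `penalty` is `NULL` it is selected on the target
#' validation split over a fixed grid (ties toward the stronger penalty).
#'
#' @param pretrained A fitted `eqg_lr` (source domain), or a list with
#'   `intercept` and `beta`.
#' @param X_train,y_train Target training data.
#' @param penalty L2 strength for the adjustments (same parameterization as
#'   [train_lr()]), or `NULL` to select on validation data.
#' @param X_val,y_val Target validation split (required when
#'   `penalty = NULL`).
#' @param penalty_grid Candidate penalties (default `10^(-1..4)`).
#' @param n_clinical Number of trailing feature columns that are clinical
#'   covariates (their adjustments are reported as `delta`).
#' @return Object of class `c("eqg_tl_lr", "eqg_lr", "eqg_model")`: combined
#'   `intercept`/`beta` (so `predict()` works as for any LR fit) plus
#'   `beta_pre`, `tau`, `gamma_pre`, `delta`, and the `penalty` used.
#' @export
fit_linear_transfer <- function(pretrained, X_train, y_train, penalty = NULL,
                                X_val = NULL, y_val = NULL,
                                penalty_grid = 10^seq(-1, 4), n_clinical = 0) {
  beta_pre <- pretrained$beta
  int_pre <- pretrained$intercept
  if (length(beta_pre) != ncol(X_train))
    stop("pretrained effects do not match the target feature count")
  if (length(unique(y_train)) < 2) stop("target labels contain one class")

  fit_one <- function(pen) {
    n <- nrow(X_train)
    lam <- pen / n
    off <- as.numeric(int_pre + X_train %*% beta_pre)
    fit <- glmnet::glmnet(X_train, y_train, family = "binomial", alpha = 0,
                          offset = off, lambda = lam * c(100, 10, 1),
                          standardize = FALSE, thresh = 1e-9, maxit = 2e5)
    cf <- as.numeric(coef(fit, s = lam))
    list(int_tau = cf[1], tau = cf[-1])
  }
  selected <- penalty
  grid_auroc <- NULL
  if (is.null(selected)) {
    if (is.null(X_val) || is.null(y_val))
      stop("penalty = NULL requires a target validation split")
    grid_auroc <- vapply(penalty_grid, function(pen) {
      f <- fit_one(pen)
      p <- stats::plogis(int_pre + f$int_tau +
                           as.numeric(X_val %*% (beta_pre + f$tau)))
      auroc(p, y_val)
    }, numeric(1))
    best <- max(grid_auroc)
    selected <- max(penalty_grid[grid_auroc >= best - 1e-12])
  }
  f <- fit_one(selected)
  m <- ncol(X_train) - n_clinical
  snp_idx <- seq_len(m)
  structure(list(kind = "LR", intercept = int_pre + f$int_tau,
                 beta = beta_pre + f$tau,
                 beta_pre = beta_pre[snp_idx], tau = f$tau[snp_idx],
                 gamma_pre = if (n_clinical) beta_pre[-snp_idx] else numeric(0),
                 delta = if (n_clinical) f$tau[-snp_idx] else numeric(0),
                 intercept_pre = int_pre, intercept_tau = f$int_tau,
                 penalty = selected, grid_auroc = grid_auroc,
                 source_fingerprint = sum(abs(beta_pre)) + abs(int_pre),
                 target_n = nrow(X_train),
                 n_features = ncol(X_train),
                 feature_names = colnames(X_train), converged = TRUE),
            class = c("eqg_tl_lr", "eqg_lr", "eqg_model"))
}

#' @export
print.eqg_tl_lr <- function(x, ...) {
  cat("<eqg_tl_lr> linear transfer fit, ", x$n_features, " features, ",
      "penalty = ", x$penalty, "\n", sep = "")
  cat("  mean |tau| = ", signif(mean(abs(x$tau)), 3), "\n", sep = "")
  invisible(x)
}
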