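# The two base predictors: L2-regularized logistic regression (ridge
# logistic, via glmnet) and the single-hidden-layer neural network trained by
# the compiled SGD core.

#' Hyperparameter configuration for the neural-network predictor
#'
#' Defaults are the training schedule used throughout the experiments: one
#' fully connected hidden layer of 100 ReLU nodes followed by dropout 0.5 and
#' a logistic output, mini-batch SGD (batch 32) with Nesterov momentum 0.9,
#' initial learning rate 0.25 decayed per update as
#' `lr_t = lr0 / (1 + 0.003 t)`, at most 200 epochs with early stopping on
#' validation accuracy (patience 200, best-epoch weights restored), and
#' L1 = L2 = 0.001 penalties on the weight matrices.
#'
#' @param hidden_nodes Hidden-layer width (0 collapses the network to a
#'   logistic-regression layer).
#' @param dropout Dropout probability in `[0, 1)` on the hidden activations.
#' @param learning_rate,lr_decay,momentum SGD schedule.
#' @param batch_size,max_epochs,patience Training loop controls.
#' @param lambda1,lambda2 L1/L2 penalty weights.
#' @param clipnorm Global gradient-norm ceiling stabilizing SGD at the large
#'   initial learning rate (0 disables clipping).
#' @param standardize Z-score features with training-split statistics before
#'   training (the statistics travel with the model and are re-applied at
#'   prediction and fine-tuning time).
#' @param seed Integer seed for initialization, batch order and dropout.
#' @return List of class `dnn_config`.
#' @export
dnn_config <- function(hidden_nodes = 100, dropout = 0.5,
                       learning_rate = 0.25, batch_size = 32,
                       max_epochs = 200, momentum = 0.9, lr_decay = 0.003,
                       patience = 200, lambda1 = 0.001, lambda2 = 0.001,
                       clipnorm = 1, standardize = TRUE, seed = 1L) {
  stopifnot(hidden_nodes >= 0, dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 0, momentum >= 0, lr_decay >= 0,
            patience >= 0, lambda1 >= 0, lambda2 >= 0, clipnorm >= 0)
  structure(list(hidden_nodes = as.integer(hidden_nodes), dropout = dropout,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 lr_decay = lr_decay, patience = as.integer(patience),
                 lambda1 = lambda1, lambda2 = lambda2, clipnorm = clipnorm,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "dnn_config")
}

#' Train the L2-regularized logistic regression predictor
#'
#' Minimizes the penalized negative log-likelihood
#' `-loglik(beta) + (l2_strength / 2) * ||beta||^2` (intercept unpenalized),
#' the objective of ridge logistic regression with regularization strength
#' `C = 1 / l2_strength` in the scikit-learn parameterization. Fitting is
#' delegated to glmnet on a decreasing ridge path ending at the requested
#' strength.
#'
#' @param X_train Numeric feature matrix.
#' @param y_train 0/1 labels (both classes must be present).
#' @param l2_strength Penalty strength (default 1, i.e. `C = 1`).
#' @return Object of class `c("eqg_lr", "eqg_model")` with `intercept`,
#'   `beta`, and a convergence flag.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 100, 2); y <- as.integer(X[, 1] > 0)
#' fit <- train_lr(X, y)
#' head(predict(fit, X))
train_lr <- function(X_train, y_train, l2_strength = 1) {
  if (length(unique(y_train)) < 2) stop("training labels contain one class")
  n <- nrow(X_train)
  lam <- l2_strength / n
  fit <- glmnet::glmnet(X_train, y_train, family = "binomial", alpha = 0,
                        lambda = lam * c(100, 10, 1), standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  cf <- as.numeric(coef(fit, s = lam))
  converged <- fit$jerr == 0
  if (!converged)
    warning("glmnet reported non-convergence (jerr = ", fit$jerr,
            "); returning the last iterate")
  structure(list(kind = "LR", intercept = cf[1], beta = cf[-1],
                 l2_strength = l2_strength, n_features = ncol(X_train),
                 feature_names = colnames(X_train), converged = converged),
            class = c("eqg_lr", "eqg_model"))
}

#' Train the neural-network predictor
#'
#' Architecture: input (K features) -> dense `hidden_nodes` with ReLU ->
#' dropout -> sigmoid output. The loss is mean binary cross-entropy plus
#' `lambda1 * sum|W| + lambda2 * sum W^2` over the weight matrices. Training
#' uses mini-batch SGD with Nesterov momentum and per-update learning-rate
#' decay; the parameters from the epoch with the best validation accuracy are
#' retained. Given the same data and config (including `config$seed`),
#' training is bit-reproducible. Inference never applies dropout.
#'
#' @param X_train,y_train Training features and 0/1 labels.
#' @param X_val,y_val Non-empty validation split monitored for early
#'   stopping / weight restoration.
#' @param config A [dnn_config()].
#' @return Object of class `c("eqg_dnn", "eqg_model")` with `weights`,
#'   per-epoch `history` (train loss incl. penalties, validation accuracy),
#'   `best_epoch`, and the config.
#' @export
train_dnn <- function(X_train, y_train, X_val, y_val, config = dnn_config()) {
  stopifnot(inherits(config, "dnn_config"))
  if (nrow(X_val) == 0) stop("validation set must be non-empty")
  if (ncol(X_val) != ncol(X_train)) stop("train/validation feature mismatch")
  scaling <- NULL
  if (config$standardize) {
    scaling <- list(center = colMeans(X_train),
                    scale = pmax(apply(X_train, 2, sd), 1e-8))
    X_train <- scale_features(X_train, scaling)
    X_val <- scale_features(X_val, scaling)
  }
  res <- dnn_train_cpp(X_train, as.numeric(y_train), X_val, as.numeric(y_val),
                       config$hidden_nodes, config$dropout,
                       config$learning_rate, config$lr_decay, config$momentum,
                       config$lambda1, config$lambda2, config$batch_size,
                       config$max_epochs, config$patience, config$seed,
                       config$clipnorm, 0L, NULL)
  structure(list(kind = "DL", hidden = config$hidden_nodes,
                 weights = res$weights, history = res$history,
                 best_epoch = res$best_epoch,
                 best_val_accuracy = res$best_val_accuracy,
                 stopped_epoch = res$stopped_epoch,
                 n_updates = res$n_updates,
                 n_features = ncol(X_train), scaling = scaling,
                 feature_names = colnames(X_train), config = config),
            class = c("eqg_dnn", "eqg_model"))
}

scale_features <- function(X, scaling) {
  if (is.null(scaling)) return(X)
  sweep(sweep(X, 2, scaling$center), 2, scaling$scale, "/")
}

check_features <- function(model, X) {
  if (ncol(X) != model$n_features)
    stop("feature count (", ncol(X), ") does not match training (",
         model$n_features, ")")
}

#' Predict case probabilities
#'
#' Deterministic inference (dropout inactive); probabilities lie strictly in
#' `(0, 1)` and batch prediction equals row-wise prediction.
#'
#' @param object A fitted `eqg_lr` / `eqg_dnn`.
#' @param X Feature matrix with the training schema.
#' @param ... Unused.
#' @return Numeric probability vector.
#' @export
predict.eqg_lr <- function(object, X, ...) {
  check_features(object, X)
  as.numeric(stats::plogis(object$intercept + X %*% object$beta))
}

#' @rdname predict.eqg_lr
#' @export
predict.eqg_dnn <- function(object, X, ...) {
  check_features(object, X)
  as.numeric(dnn_predict_cpp(scale_features(X, object$scaling),
                             object$hidden, object$weights))
}

#' @export
coef.eqg_lr <- function(object, ...) {
  cf <- c(object$intercept, object$beta)
  names(cf) <- c("(Intercept)",
                 object$feature_names %||% paste0("x", seq_along(object$beta)))
  cf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eqg_lr <- function(x, ...) {
  cat("<eqg_lr> ridge logistic regression, ", x$n_features,
      " features, l2_strength = ", x$l2_strength, "\n", sep = "")
  invisible(x)
}

#' @export
print.eqg_dnn <- function(x, ...) {
  cat("<eqg_dnn> ", x$n_features, " -> ", x$hidden,
      " (ReLU, dropout ", x$config$dropout, ") -> 1 (sigmoid)\n", sep = "")
  cat("  trained ", x$stopped_epoch, " epochs; best validation accuracy ",
      round(x$best_val_accuracy, 3), " at epoch ", x$best_epoch, "\n",
      sep = "")
  invisible(x)
}

#' Plot the neural-network training history
#' @param x A fitted `eqg_dnn`.
#' @param ... Passed to [plot()].
#' @export
plot.eqg_dnn <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss (incl. penalties)", ...)
  plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
       ylab = "validation accuracy", ...)
  abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Serialize / restore a fitted predictor as plain text
#'
#' Portable JSON-free text container: a header with the model kind and
#' config echo, then the flattened parameters at full precision.
#'
#' @param model A fitted `eqg_model`.
#' @param path File path.
#' @return `write_model`: the path, invisibly. `read_model`: the restored
#'   model.
#' @export
write_model <- function(model, path) {
  lines <- c(paste0("kind\t", model$kind),
             paste0("n_features\t", model$n_features))
  if (model$kind == "LR") {
    lines <- c(lines, paste0("l2_strength\t", model$l2_strength),
               paste0("intercept\t", sprintf("%.17g", model$intercept)),
               paste0("beta\t", paste(sprintf("%.17g", model$beta),
                                      collapse = ",")))
  } else {
    cfg <- model$config
    lines <- c(lines,
               paste0("config\t", paste(names(unclass(cfg)),
                                        unlist(cfg), sep = "=",
                                        collapse = ",")),
               paste0("hidden\t", model$hidden),
               paste0("W2\t", paste(sprintf("%.17g", model$weights$W2),
                                    collapse = ",")),
               paste0("b2\t", sprintf("%.17g", model$weights$b2)))
    if (!is.null(model$scaling)) {
      lines <- c(lines,
                 paste0("center\t", paste(sprintf("%.17g", model$scaling$center),
                                          collapse = ",")),
                 paste0("scale\t", paste(sprintf("%.17g", model$scaling$scale),
                                         collapse = ",")))
    }
    if (model$hidden > 0) {
      lines <- c(lines,
                 paste0("W1\t", paste(sprintf("%.17g", model$weights$W1),
                                      collapse = ",")),
                 paste0("b1\t", paste(sprintf("%.17g", model$weights$b1),
                                      collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t")
  vals <- setNames(vapply(fields, function(f) f[2], character(1)),
                   vapply(fields, function(f) f[1], character(1)))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  n_features <- as.integer(vals[["n_features"]])
  if (vals[["kind"]] == "LR") {
    structure(list(kind = "LR", intercept = num("intercept"),
                   beta = num("beta"), l2_strength = as.numeric(vals[["l2_strength"]]),
                   n_features = n_features, feature_names = NULL,
                   converged = TRUE),
              class = c("eqg_lr", "eqg_model"))
  } else {
    hidden <- as.integer(vals[["hidden"]])
    weights <- list(W2 = num("W2"), b2 = num("b2"))
    if (hidden > 0) {
      weights$W1 <- matrix(num("W1"), n_features, hidden)
      weights$b1 <- num("b1")
    }
    scaling <- if ("center" %in% names(vals))
      list(center = num("center"), scale = num("scale")) else NULL
    structure(list(kind = "DL", hidden = hidden, weights = weights,
                   history = NULL, best_epoch = NA_integer_,
                   best_val_accuracy = NA_real_, stopped_epoch = NA_integer_,
                   n_features = n_features, scaling = scaling,
                   feature_names = NULL, config = NULL),
              class = c("eqg_dnn", "eqg_model"))
  }
}
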