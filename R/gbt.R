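#' Gradient-boosted tree parameters
#'
#' Defaults mirror common gradient-boosting defaults (100 rounds,
#' learning rate 0.1, depth-wise trees, minimum 20 samples per leaf, no
#' regularization) with the imbalance-reweighting flag on: when
#' `unbalance = TRUE` the positive class is up-weighted by the
#' negative/positive weight ratio, the equivalent of LightGBM-style
#' `is_unbalance`.
#'
#' @param nrounds boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth maximum tree depth.
#' @param min_child minimum samples per leaf.
#' @param lambda L2 regularization on leaf values.
#' @param min_gain minimum split gain.
#' @param unbalance up-weight positives to balance total class weight.
#' @param subsample,colsample stochastic row/column sampling fractions;
#'   1 (the default) keeps training fully deterministic.
#' @param early_stopping_rounds stop after this many rounds without
#'   validation-loss improvement (0 disables; requires a validation set).
#' @return named list of parameters.
#' @export
gbt_params <- function(nrounds = 100L, learning_rate = 0.1, max_depth = 6L,
                       min_child = 20L, lambda = 0, min_gain = 1e-10,
                       unbalance = TRUE, subsample = 1, colsample = 1,
                       early_stopping_rounds = 0L) {
  list(nrounds = as.integer(nrounds), learning_rate = learning_rate,
       max_depth = as.integer(max_depth), min_child = as.integer(min_child),
       lambda = lambda, min_gain = min_gain, unbalance = isTRUE(unbalance),
       subsample = subsample, colsample = colsample,
       early_stopping_rounds = as.integer(early_stopping_rounds))
}

#' Fit a gradient-boosted binary classifier
#'
#' Exact-greedy gradient boosting on decision trees with logistic loss
#' (implemented in C++). Deterministic for given inputs unless
#' `subsample`/`colsample` < 1, in which case `seed` controls sampling.
#'
#' @param X numeric feature matrix (rows = instances).
#' @param y 0/1 (or logical) response.
#' @param params see [gbt_params()].
#' @param valid optional list `(X, y)` used for early stopping.
#' @param seed integer seed for row/column subsampling.
#' @return object of class `gbt_model`.
#' @export
gbt_fit <- function(X, y, params = gbt_params(), valid = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  w <- rep(1, length(y))
  if (params$unbalance && any(y == 1) && any(y == 0))
    w[y == 1] <- sum(y == 0) / sum(y == 1)
  Xv <- NULL; yv <- NULL
  if (!is.null(valid)) {
    Xv <- as.matrix(valid$X); yv <- as.numeric(valid$y)
  }
  fit <- .gbt_fit_cpp(X, y, w, params$nrounds, params$learning_rate,
                      params$max_depth, params$min_child, params$lambda,
                      params$min_gain, params$subsample, params$colsample,
                      as.integer(seed), Xv, yv, params$early_stopping_rounds)
  structure(list(fit = fit, params = params, n_features = ncol(X),
                 feature_names = colnames(X)), class = "gbt_model")
}

#' Predict from a gradient-boosted model
#'
#' @param object a `gbt_model`.
#' @param newdata numeric matrix with the training feature layout.
#' @param type `"response"` for probabilities, `"raw"` for boosting scores.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) stop("feature count mismatch")
  raw <- .gbt_predict_cpp(object$fit, newdata)
  if (type == "raw") raw else 1 / (1 + exp(-raw))
}

#' @export
print.gbt_model <- function(x, ...) {
  cat(sprintf("<gbt_model> %d trees, %d features (best_iter %d)\n",
              length(x$fit$trees), x$n_features, x$fit$best_iter))
  invisible(x)
}

#' Pluggable classifier backend
#'
#' The experiment logic is backend-agnostic: a backend is a list with
#' `fit(X, y, valid, seed)` returning an opaque model and
#' `predict(model, X)` returning positive-class probabilities. The default
#' backend is the in-package gradient-boosted tree learner; a logistic
#' (glm) backend is provided for cross-checks.
#'
#' @param name `"gbt"` or `"logistic"`.
#' @param params backend parameters ([gbt_params()] for `"gbt"`).
#' @return backend object (list of closures) of class `har_backend`.
#' @export
gbt_backend <- function(name = c("gbt", "logistic"), params = gbt_params()) {
  name <- match.arg(name)
  if (name == "gbt") {
    be <- list(
      name = "gbt",
      fit = function(X, y, valid = NULL, seed = 1L)
        gbt_fit(X, y, params = params, valid = valid, seed = seed),
      predict = function(model, X) predict(model, X, type = "response"))
  } else {
    be <- list(
      name = "logistic",
      fit = function(X, y, valid = NULL, seed = 1L) {
        df <- as.data.frame(X); df$.y <- y
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(model, X)
        as.numeric(suppressWarnings(stats::predict(model, as.data.frame(X),
                                                   type = "response"))))
  }
  structure(be, class = "har_backend")
}
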