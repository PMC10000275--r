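# The five clock regressors behind a single fit/predict surface.
# Linear regression uses stats::lm.fit, elastic net uses glmnet (same
# penalty parameterization as scikit-learn: lambda = reg_strength,
# alpha = l1_ratio, on standardized features). The three tree ensembles —
# random forest (bootstrap-aggregated unpruned CART), gradient boosting
# (least-squares boosting of depth-3 trees) and AdaBoost.R2 (linear loss,
# weighted-median prediction) — are built on the Rcpp CART in
# src/regtree.cpp because no tree-ensemble package is assumed; their
# conventions (defaults, impurity importance summing to one) follow the
# mainstream ML-library behaviour.

CLOCK_METHODS <- c("linear_regression", "elastic_net", "adaptive_boosting",
                   "gradient_boosting", "random_forest")

#' Specification of one clock regressor
#'
#' @param method One of `linear_regression`, `elastic_net`,
#'   `adaptive_boosting`, `gradient_boosting`, `random_forest`.
#' @param n_estimators Number of weak learners (tree methods).
#' @param learning_rate Shrinkage for gradient boosting / AdaBoost.
#' @param max_depth Tree depth: default 3 for boosting methods,
#'   unrestricted (`Inf`) for the random forest.
#' @param l1_ratio Elastic-net mixing (1 = lasso, 0 = ridge).
#' @param reg_strength Elastic-net overall penalty strength.
#' @param seed Integer seed for the stochastic ensembles.
#' @return A `model_spec` list.
#' @export
model_spec <- function(method = CLOCK_METHODS,
                       n_estimators = 100,
                       learning_rate = 0.1,
                       max_depth = NULL,
                       l1_ratio = 0.5,
                       reg_strength = 1.0,
                       seed = 1L) {
  method <- match.arg(method)
  if (method %in% c("adaptive_boosting", "gradient_boosting",
                    "random_forest") && n_estimators < 1) {
    abort("tree methods need n_estimators >= 1")
  }
  max_depth <- max_depth %||%
    switch(method, random_forest = Inf, adaptive_boosting = 3,
           gradient_boosting = 3, Inf)
  structure(list(method = method, n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate, max_depth = max_depth,
                 l1_ratio = l1_ratio, reg_strength = reg_strength,
                 seed = as.integer(seed)),
            class = "model_spec")
}

depth_arg <- function(max_depth) {
  if (is.infinite(max_depth)) -1L else as.integer(max_depth)
}

fit_tree <- function(X, y, w = NULL, max_depth = Inf) {
  w <- w %||% rep(1, length(y))
  cpp_tree_fit(X, y, w, depth_arg(max_depth))
}

fit_random_forest <- function(X, y, spec) {
  n <- nrow(X)
  trees <- purrr::map(seq_len(spec$n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_tree(X[idx, , drop = FALSE], y[idx], max_depth = spec$max_depth)
  })
  imp <- Reduce(`+`, purrr::map(trees, "importance")) / length(trees)
  list(trees = trees, importance = imp)
}

predict_random_forest <- function(fit, X) {
  preds <- vapply(fit$trees, function(tr) cpp_tree_predict(tr, X),
                  numeric(nrow(X)))
  rowMeans(matrix(preds, nrow = nrow(X)))
}

fit_gradient_boosting <- function(X, y, spec) {
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", spec$n_estimators)
  imp <- numeric(ncol(X))
  for (b in seq_len(spec$n_estimators)) {
    tr <- fit_tree(X, resid, max_depth = spec$max_depth)
    trees[[b]] <- tr
    resid <- resid - spec$learning_rate * cpp_tree_predict(tr, X)
    imp <- imp + tr$importance
  }
  list(f0 = f0, trees = trees, learning_rate = spec$learning_rate,
       importance = imp / spec$n_estimators)
}

predict_gradient_boosting <- function(fit, X) {
  out <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) {
    out <- out + fit$learning_rate * cpp_tree_predict(tr, X)
  }
  out
}

# AdaBoost.R2 (Drucker 1997) with linear loss: trees are trained on
# weight-resampled data; prediction is the weighted median across
# estimators with weights log(1/beta).
fit_adaboost <- function(X, y, spec) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  for (b in seq_len(spec$n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tr <- fit_tree(X[idx, , drop = FALSE], y[idx],
                   max_depth = spec$max_depth)
    pred <- cpp_tree_predict(tr, X)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) {
      trees <- c(trees, list(tr))
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) {
      if (length(trees) == 0) {
        trees <- list(tr)
        betas <- 0.5 # keep a single weak tree rather than fail
      }
      break
    }
    beta <- lbar / (1 - lbar)
    trees <- c(trees, list(tr))
    betas <- c(betas, beta)
    w <- w * beta^((1 - loss) * spec$learning_rate)
    w <- w / sum(w)
  }
  est_w <- log(1 / betas)
  imp <- Reduce(`+`, purrr::map2(trees, est_w,
                                 function(tr, ew) tr$importance * ew))
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  list(trees = trees, est_weights = est_w, importance = imp)
}

predict_adaboost <- function(fit, X) {
  preds <- matrix(vapply(fit$trees, function(tr) cpp_tree_predict(tr, X),
                         numeric(nrow(X))), nrow = nrow(X))
  wts <- fit$est_weights
  apply(preds, 1, function(p) {
    ord <- order(p)
    cw <- cumsum(wts[ord])
    p[ord][which(cw >= 0.5 * sum(wts))[1]]
  })
}

normalize_importance <- function(imp, feature_names) {
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  setNames(imp, feature_names)
}

#' Fit one clock regressor
#'
#' Features are samples x genes; the response is chronological age.
#' Elastic net standardizes features internally; tree methods work on the
#' raw scale. Deterministic given `spec$seed`.
#'
#' @param X Numeric matrix, samples x genes.
#' @param y Numeric ages.
#' @param spec A [model_spec()].
#' @return An `snc_model` with a [predict][predict.snc_model] method; tree
#'   methods carry an impurity `importance` vector normalized to sum to 1.
#' @export
fit_clock_model <- function(X, y, spec = model_spec("random_forest")) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fit <- with_seed(spec$seed, switch(
    spec$method,
    linear_regression = {
      lm.fit(cbind(`(Intercept)` = 1, X), y)
    },
    elastic_net = {
      glmnet::glmnet(X, y, alpha = spec$l1_ratio,
                     lambda = spec$reg_strength, standardize = TRUE)
    },
    random_forest = fit_random_forest(X, y, spec),
    gradient_boosting = fit_gradient_boosting(X, y, spec),
    adaptive_boosting = fit_adaboost(X, y, spec)
  ))
  importance <- if (spec$method %in% c("random_forest", "gradient_boosting",
                                       "adaptive_boosting")) {
    normalize_importance(fit$importance, colnames(X))
  } else {
    NULL
  }
  structure(list(spec = spec, fit = fit, features = colnames(X),
                 importance = importance),
            class = "snc_model")
}

#' Predict ages from a fitted clock model
#'
#' @param object An `snc_model`.
#' @param newdata Numeric matrix, samples x genes, with the training
#'   features (by name when available).
#' @param ... Unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.snc_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  switch(object$spec$method,
    linear_regression = {
      cf <- object$fit$coefficients
      cf[is.na(cf)] <- 0 # collinear features drop out of the fit
      as.numeric(cbind(1, X) %*% cf)
    },
    elastic_net = as.numeric(predict(object$fit, newx = X)),
    random_forest = predict_random_forest(object$fit, X),
    gradient_boosting = predict_gradient_boosting(object$fit, X),
    adaptive_boosting = predict_adaboost(object$fit, X)
  )
}

#' @export
print.snc_model <- function(x, ...) {
  cat("<snc_model> method =", x$spec$method, "on",
      length(x$features %||% character()), "features\n")
  invisible(x)
}
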