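# broom-style tidiers for the package's fitted objects.

#' Tidy a cross-validated clock fit
#'
#' @param x An `snc_cv` from [fit_predict_cv()].
#' @param ... Unused.
#' @return Tibble of per-fold metrics (`fold`, `r2`, `rmse`, `mae`).
#' @export
tidy.snc_cv <- function(x, ...) {
  x$metrics
}

#' One-row summary of a cross-validated clock fit
#'
#' @param x An `snc_cv`.
#' @param ... Unused.
#' @return One-row tibble: `method`, mean `r2`, `rmse`, `mae`, `k`,
#'   `n_genes`.
#' @export
glance.snc_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(method = x$spec$method), x$summary,
                   tibble::tibble(k = nrow(x$metrics),
                                  n_genes = length(x$model$features)))
}

#' Tidy a fitted clock model
#'
#' @param x An `snc_model` from [fit_clock_model()].
#' @param ... Unused.
#' @return Tibble of per-gene importance (tree methods) or coefficients
#'   (linear methods).
#' @export
tidy.snc_model <- function(x, ...) {
  if (!is.null(x$importance)) {
    return(tibble::tibble(gene_id = names(x$importance),
                          importance = as.numeric(x$importance)) |>
             dplyr::arrange(dplyr::desc(.data$importance)))
  }
  cf <- switch(x$spec$method,
    linear_regression = x$fit$coefficients,
    elastic_net = {
      b <- as.matrix(coef(x$fit))
      setNames(b[, 1], rownames(b))
    }
  )
  tibble::tibble(term = names(cf), estimate = as.numeric(cf))
}

#' Tidy an empirical-Bayes batch model
#'
#' @param x An `snc_batch_model` from [combat_correct()].
#' @param ... Unused.
#' @return Long tibble of per-gene per-batch location/scale estimates,
#'   raw and shrunk.
#' @export
tidy.snc_batch_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$batches), function(j) {
    tibble::tibble(
      gene_id = rownames(x$gamma_raw),
      batch = x$batches[j],
      gamma_hat = x$gamma_raw[, j],
      delta2_hat = x$delta2_raw[, j],
      gamma_star = x$gamma_star[, j],
      delta2_star = x$delta2_star[, j]
    )
  })
}

#' Batch-level prior hyperparameters of an empirical-Bayes batch model
#'
#' @param x An `snc_batch_model`.
#' @param ... Unused.
#' @return One row per batch with the normal / inverse-gamma prior
#'   hyperparameters.
#' @export
glance.snc_batch_model <- function(x, ...) {
  purrr::imap_dfr(x$priors, function(p, b) {
    tibble::tibble(batch = b, gamma_bar = p$gamma_bar, tau2 = p$tau2,
                   a_prior = p$a, b_prior = p$b)
  })
}
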