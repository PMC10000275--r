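# Parametric empirical-Bayes batch correction (the ComBat model of
# Johnson, Li & Rabinovic 2007): per-gene location/scale batch effects are
# estimated after standardization, shrunk toward batch-level normal /
# inverse-gamma priors fitted by method of moments, and removed.

#' Empirical-Bayes batch correction of an expression matrix
#'
#' Operates by default on `log2(CPM + 1)` (the additive scale the model
#' assumes) and maps back to CPM by exponentiation, flooring at zero;
#' `scale = "raw"` corrects the supplied values directly for sensitivity
#' analysis. The biological model defaults to an intercept only; pass
#' `covariates` (a design matrix or a data frame of per-sample covariates)
#' to protect biological signal such as age group.
#'
#' @param expr Expression tibble (`gene_id` + sample columns) of CPM
#'   values.
#' @param batch Character/factor of batch labels, one per sample (or the
#'   name of a column in `covariates`... supply directly).
#' @param covariates Optional data frame or matrix of biological
#'   covariates to retain (converted to a model matrix; no intercept
#'   needed).
#' @param scale `"log2cpm"` (default) or `"raw"`.
#' @param tol Convergence tolerance of the EB iteration.
#' @param max_iter Maximum EB iterations per batch.
#' @return List with `expr` (corrected tibble, same shape) and `model`
#'   (class `snc_batch_model`: per-gene estimates, per-batch raw and
#'   shrunk location/scale effects and prior hyperparameters).
#' @export
combat_correct <- function(expr, batch, covariates = NULL,
                           scale = c("log2cpm", "raw"),
                           tol = 1e-4, max_iter = 100) {
  scale <- match.arg(scale)
  Y <- expr_to_matrix(expr)
  batch <- as.character(batch)
  if (length(batch) != ncol(Y)) {
    abort("`batch` must give one label per sample column")
  }
  batches <- sort(unique(batch))
  if (length(batches) < 2) {
    inform("single batch: nothing to correct, returning input unchanged")
    return(list(expr = expr, model = NULL))
  }
  n_i <- table(factor(batch, levels = batches))
  if (any(n_i < 2)) {
    abort(paste0("batch(es) with a single sample: ",
                 paste(names(n_i)[n_i < 2], collapse = ", "),
                 "; merge or drop them before correction"))
  }
  if (scale == "log2cpm") Y <- log2(Y + 1)

  # design: batch cell-means block + optional covariates (no intercept in
  # the covariate block; columns centred so they don't absorb the mean)
  Xb <- stats::model.matrix(~ 0 + factor(batch, levels = batches))
  colnames(Xb) <- batches
  Xc <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xc <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    if (qr(cbind(Xb, Xc))$rank < ncol(Xb) + ncol(Xc)) {
      abort("covariates are confounded with batch")
    }
  }
  X <- cbind(Xb, Xc)
  n <- ncol(Y)
  G <- nrow(Y)

  # per-gene OLS fit; zero-variance genes pass through untouched
  fit <- lm.fit(X, t(Y))
  B_hat <- t(fit$coefficients)           # G x ncol(X)
  gamma_hat <- B_hat[, seq_along(batches), drop = FALSE]
  weights <- as.numeric(n_i) / n
  alpha_hat <- as.numeric(gamma_hat %*% weights)
  beta_hat <- if (is.null(Xc)) NULL else
    B_hat[, -seq_along(batches), drop = FALSE]
  fitted_bio <- alpha_hat +
    if (is.null(Xc)) 0 else beta_hat %*% t(Xc)
  resid <- Y - t(X %*% t(B_hat))
  sigma2 <- rowMeans(resid^2)
  degenerate <- sigma2 < 1e-12
  if (any(degenerate)) {
    warn(paste0(sum(degenerate),
                " zero-variance gene(s) passed through unadjusted"))
  }
  sig <- sqrt(pmax(sigma2, 1e-12))
  Z <- (Y - fitted_bio) / sig

  idx_by_batch <- lapply(batches, function(b) which(batch == b))
  gamma_raw <- delta2_raw <- gamma_star <- delta2_star <-
    matrix(NA_real_, G, length(batches), dimnames = list(rownames(Y), batches))
  priors <- list()
  for (j in seq_along(batches)) {
    cols <- idx_by_batch[[j]]
    ni <- length(cols)
    Zi <- Z[, cols, drop = FALSE]
    g_hat <- rowMeans(Zi)
    d_hat <- apply(Zi, 1, var)
    gamma_raw[, j] <- g_hat
    delta2_raw[, j] <- d_hat
    # method-of-moments hyperpriors across genes
    g_bar <- mean(g_hat)
    t2 <- var(g_hat)
    m <- mean(d_hat)
    s2 <- var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    priors[[batches[j]]] <- list(gamma_bar = g_bar, tau2 = t2,
                                 a = a_prior, b = b_prior)
    # EB conditional updates, iterated to convergence
    g_old <- g_hat
    d_old <- d_hat
    sse0 <- rowSums(Zi^2)
    sum_z <- rowSums(Zi)
    change <- Inf
    iter <- 0
    while (change > tol && iter < max_iter) {
      g_new <- (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
      sse <- sse0 - 2 * g_new * sum_z + ni * g_new^2
      d_new <- (b_prior + 0.5 * sse) / (ni / 2 + a_prior - 1)
      change <- max(max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8)),
                    max(abs(d_new - d_old) / pmax(abs(d_old), 1e-8)))
      g_old <- g_new
      d_old <- d_new
      iter <- iter + 1
    }
    gamma_star[, j] <- g_old
    delta2_star[, j] <- d_old
  }

  Ystar <- Y
  for (j in seq_along(batches)) {
    cols <- idx_by_batch[[j]]
    adj <- (Z[, cols, drop = FALSE] - gamma_star[, j]) /
      sqrt(delta2_star[, j])
    Ystar[, cols] <- adj * sig +
      (if (is.matrix(fitted_bio)) fitted_bio[, cols, drop = FALSE]
       else fitted_bio)
  }
  if (any(degenerate)) Ystar[degenerate, ] <- Y[degenerate, ]
  if (scale == "log2cpm") Ystar <- pmax(2^Ystar - 1, 0)

  model <- structure(list(
    batches = batches, n_per_batch = as.integer(n_i),
    alpha_hat = alpha_hat, beta_hat = beta_hat, sigma2 = sigma2,
    gamma_raw = gamma_raw, delta2_raw = delta2_raw,
    gamma_star = gamma_star, delta2_star = delta2_star,
    priors = priors, scale = scale
  ), class = "snc_batch_model")
  list(expr = matrix_to_expr(Ystar), model = model)
}

#' @export
print.snc_batch_model <- function(x, ...) {
  cat("<snc_batch_model> ", length(x$alpha_hat), " genes, ",
      length(x$batches), " batches (",
      paste(x$batches, collapse = ", "), "), scale = ", x$scale, "\n",
      sep = "")
  invisible(x)
}

#' Principal-component batch diagnostic
#'
#' Column-centred SVD scores of samples on the first two principal
#' components, labeled by batch and age group, plus the share of PC1
#' variance explained by batch (R-squared of a one-way fit) — the standard
#' before/after check that batch structure dominates or has been removed.
#'
#' @param expr Expression tibble; the decomposition runs on
#'   `log2(x + 1)` of the values when `log = TRUE` (default).
#' @param meta Sample metadata with `batch` and `age`.
#' @param grouping An [age_grouping()].
#' @param log Log-transform before the SVD.
#' @return Tibble of class `snc_pca` with `sample_id`, `PC1`, `PC2`,
#'   `batch`, `age_group`; attributes `var_explained` (length 2) and
#'   `batch_r2` (share of PC1 variance explained by batch), plus
#'   `degenerate` when the matrix has no variance.
#' @export
pca_diagnostic <- function(expr, meta, grouping = age_grouping(),
                           log = TRUE) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 3) abort("need at least three samples")
  meta <- align_meta(expr, meta)
  x <- t(if (log) log2(m + 1) else m)
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  degenerate <- sum(sv$d^2) < 1e-12
  if (degenerate) {
    scores <- matrix(0, nrow(x), 2)
    ve <- c(NA_real_, NA_real_)
    r2 <- NA_real_
  } else {
    scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
    ve <- (sv$d^2 / sum(sv$d^2))[1:2]
    fit <- lm(scores[, 1] ~ factor(meta$batch))
    r2 <- summary(fit)$r.squared
  }
  out <- tibble::tibble(
    sample_id = rownames(x) %||% meta$sample_id,
    PC1 = scores[, 1], PC2 = scores[, 2],
    batch = meta$batch,
    age_group = assign_age_group(meta$age, grouping)
  )
  structure(out, class = c("snc_pca", class(out)),
            var_explained = ve, batch_r2 = r2, degenerate = degenerate)
}

#' Share of PC1 variance explained by batch
#'
#' @param pca An `snc_pca` from [pca_diagnostic()].
#' @return The one-way R-squared of PC1 on batch.
#' @export
batch_r2 <- function(pca) attr(pca, "batch_r2")
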