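# Age-prediction modeling: age-group-stratified k-fold cross-validation,
# out-of-fold R^2 / RMSE / MAE, impurity importance from a full-data
# refit, and the gender-split transfer evaluation.

#' Age-group-stratified fold assignment
#'
#' Samples are partitioned into `k` folds so that within every age group
#' the fold sizes differ by at most one (groups smaller than `k` are
#' spread as evenly as possible).
#'
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param k Number of folds.
#' @param grouping An [age_grouping()].
#' @param seed Integer seed (shuffling within groups).
#' @return Tibble with `sample_id`, `age_group`, `fold` (1..k).
#' @export
stratified_age_folds <- function(meta, k = 5, grouping = age_grouping(),
                                 seed = 1L) {
  if (k < 2) abort("k must be >= 2")
  grp <- assign_age_group(meta$age, grouping)
  if (anyNA(grp)) abort("every sample must fall into an age group")
  if (any(!levels(grp) %in% grp)) {
    warn("some age groups are empty")
  }
  fold <- integer(nrow(meta))
  with_seed(seed, {
    for (lab in levels(grp)) {
      idx <- which(grp == lab)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      # round-robin with a random starting fold keeps remainders unbiased
      start <- sample.int(k, 1)
      fold[idx] <- ((seq_along(idx) - 1 + start - 1) %% k) + 1
    }
  })
  tibble::tibble(sample_id = meta$sample_id, age_group = grp, fold = fold)
}

#' Regression metrics on held-out predictions
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return One-row tibble with `r2` (1 - SSE/SST), `rmse` and `mae`
#'   (years).
#' @export
evaluate_predictions <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  err <- predicted - actual
  sst <- sum((actual - mean(actual))^2)
  tibble::tibble(
    r2 = 1 - sum(err^2) / sst,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err))
  )
}

expr_to_features <- function(expr, meta) {
  m <- expr_to_matrix(expr)
  X <- t(m)
  meta <- align_meta(expr, meta)
  list(X = X, meta = meta)
}

#' Cross-validated fit of one clock regressor
#'
#' For each fold, trains on the remaining samples and predicts the
#' held-out ages; impurity importance comes from a final fit on all data
#' (set `fold_importance = TRUE` to average over fold fits instead).
#'
#' @param expr Expression tibble of the screened (age-associated) genes.
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param spec A [model_spec()].
#' @param folds Optional fold tibble from [stratified_age_folds()];
#'   computed at `k` folds otherwise.
#' @param k,grouping,seed Passed to [stratified_age_folds()] when `folds`
#'   is missing; `seed` defaults to the spec's seed.
#' @param fold_importance Average tree importance over fold fits instead
#'   of refitting on all data.
#' @return An `snc_cv` object: fold and averaged metrics, out-of-fold
#'   predictions, the normalized importance table and the final model.
#'   Use [tidy()] / [glance()] to extract metrics.
#' @export
fit_predict_cv <- function(expr, meta, spec = model_spec("random_forest"),
                           folds = NULL, k = 5, grouping = age_grouping(),
                           seed = NULL, fold_importance = FALSE) {
  fm <- expr_to_features(expr, meta)
  X <- fm$X
  ages <- fm$meta$age
  n <- nrow(X)
  folds <- folds %||% stratified_age_folds(fm$meta, k = k,
                                           grouping = grouping,
                                           seed = seed %||% spec$seed)
  fold_id <- folds$fold[match(rownames(X), folds$sample_id)]
  if (anyNA(fold_id)) abort("folds do not cover every sample")
  kk <- max(fold_id)
  if (n < kk) abort("fewer samples than folds")

  oof <- rep(NA_real_, n)
  fold_fits <- list()
  fold_metrics <- purrr::map_dfr(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    fit <- fit_clock_model(X[tr, , drop = FALSE], ages[tr], spec)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    oof[!tr] <<- pred
    fold_fits[[as.character(f)]] <<- fit
    dplyr::bind_cols(tibble::tibble(fold = f),
                     evaluate_predictions(pred, ages[!tr]))
  })
  final_fit <- fit_clock_model(X, ages, spec)
  importance <- if (is.null(final_fit$importance)) {
    NULL
  } else if (fold_importance) {
    imp <- Reduce(`+`, purrr::map(fold_fits, "importance")) /
      length(fold_fits)
    normalize_importance(imp, names(imp))
  } else {
    final_fit$importance
  }
  imp_tbl <- if (is.null(importance)) NULL else {
    tibble::tibble(gene_id = names(importance),
                   importance = as.numeric(importance)) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  }
  structure(list(
    spec = spec,
    metrics = fold_metrics,
    summary = dplyr::summarise(fold_metrics,
                               dplyr::across(c("r2", "rmse", "mae"), mean)),
    predictions = tibble::tibble(sample_id = rownames(X), age = ages,
                                 fold = fold_id, predicted = oof),
    importance = imp_tbl,
    model = final_fit,
    folds = folds
  ), class = "snc_cv")
}

#' @export
print.snc_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<snc_cv> %s: mean out-of-fold R2 = %.3f, RMSE = %.2f y, MAE = %.2f y (%d folds)\n",
              x$spec$method, s$r2, s$rmse, s$mae, nrow(x$metrics)))
  invisible(x)
}

#' Cross-gender transfer evaluation
#'
#' Trains on one gender's samples and evaluates on the other, in both
#' directions; per-direction importances can feed [importance_ranks()] to
#' obtain gender-specific core sncRNA lists.
#'
#' @param expr Expression tibble of screened genes.
#' @param meta Sample metadata with `sample_id`, `age`, `gender`.
#' @param spec A [model_spec()].
#' @return An `snc_gender_eval`: `metrics` tibble (one row per direction)
#'   and `importance` (named list of per-direction importance tibbles,
#'   tree methods only).
#' @export
cross_gender_eval <- function(expr, meta,
                              spec = model_spec("random_forest")) {
  fm <- expr_to_features(expr, meta)
  genders <- unique(fm$meta$gender)
  if (length(genders) < 2) abort("both genders must be present")
  dirs <- list(male_to_female = c("male", "female"),
               female_to_male = c("female", "male"))
  res <- purrr::map(dirs, function(d) {
    tr <- fm$meta$gender == d[1]
    te <- fm$meta$gender == d[2]
    fit <- fit_clock_model(fm$X[tr, , drop = FALSE], fm$meta$age[tr], spec)
    pred <- predict(fit, fm$X[te, , drop = FALSE])
    list(metrics = evaluate_predictions(pred, fm$meta$age[te]),
         importance = fit$importance)
  })
  metrics <- purrr::imap_dfr(res, function(r, nm) {
    dplyr::bind_cols(tibble::tibble(direction = nm), r$metrics)
  })
  importance <- purrr::map(res, function(r) {
    if (is.null(r$importance)) return(NULL)
    tibble::tibble(gene_id = names(r$importance),
                   importance = as.numeric(r$importance)) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  })
  structure(list(spec = spec, metrics = metrics, importance = importance),
            class = "snc_gender_eval")
}

#' @export
print.snc_gender_eval <- function(x, ...) {
  cat("<snc_gender_eval> method =", x$spec$method, "\n")
  print(x$metrics)
  invisible(x)
}
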