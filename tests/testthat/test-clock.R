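test_that("stratified folds balance every age group to within one sample", {
  meta <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:50),
    age = c(rep(25, 20), rep(45, 20), rep(70, 10))
  )
  f <- stratified_age_folds(meta, k = 5, seed = 1)
  tab <- table(f$age_group, f$fold)
  expect_true(all(tab["young", ] == 4))
  expect_true(all(tab["adult", ] == 4))
  expect_true(all(tab["aged", ] == 2))
  expect_setequal(f$sample_id, meta$sample_id)
  expect_identical(anyDuplicated(f$sample_id), 0L)

  # 7 aged samples over 5 folds: sizes in {1, 2}
  meta7 <- tibble::tibble(sample_id = sprintf("A%d", 1:27),
                          age = c(rep(25, 10), rep(45, 10), rep(70, 7)))
  f7 <- stratified_age_folds(meta7, k = 5, seed = 2)
  aged_sizes <- as.integer(table(f7$fold[f7$age_group == "aged"]))
  expect_true(all(aged_sizes %in% 1:2))
  for (g in levels(f7$age_group)) {
    sz <- table(factor(f7$fold[f7$age_group == g], levels = 1:5))
    expect_lte(diff(range(sz)), 1)
  }
  expect_error(stratified_age_folds(meta, k = 1), ">= 2")
})

test_that("evaluation metrics match hand-computed values and RMSE >= MAE", {
  perfect <- evaluate_predictions(c(20, 30, 40), c(20, 30, 40))
  expect_equal(unlist(perfect), c(r2 = 1, rmse = 0, mae = 0))

  actual <- c(20, 30, 40)
  const <- evaluate_predictions(rep(mean(actual), 3), actual)
  expect_equal(const$r2, 0)

  hand <- evaluate_predictions(c(20, 30, 40), c(22, 30, 38))
  expect_equal(hand$rmse, sqrt(8 / 3))
  expect_equal(hand$mae, 4 / 3)

  set.seed(4)
  for (i in 1:20) {
    p <- rnorm(30, 50, 10)
    a <- rnorm(30, 50, 10)
    m <- evaluate_predictions(p, a)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("a perfect single-feature predictor yields R2 = 1, RMSE = MAE = 0", {
  ages <- round(runif(40, 20, 99))
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:40), age = ages)
  expr <- sncclock:::matrix_to_expr(
    matrix(ages, 1, 40, dimnames = list("age_gene", meta$sample_id)))
  cv <- fit_predict_cv(expr, meta, model_spec("linear_regression"),
                       k = 5, seed = 3)
  expect_equal(cv$summary$r2, 1)
  expect_equal(cv$summary$rmse, 0)
  expect_equal(cv$summary$mae, 0)
})

test_that("label-permuted ages destroy held-out performance", {
  co <- simulate_cohort(quick_config(seed = 41, n_samples = 100))
  e <- preprocess_cohort(co, batch_correct = FALSE)
  es <- e[e$gene_id %in% true_genes(co), ]
  meta_perm <- co$meta
  set.seed(9)
  meta_perm$age <- sample(meta_perm$age)
  for (method in c("gradient_boosting", "random_forest", "elastic_net")) {
    cv <- fit_predict_cv(es, meta_perm,
                         model_spec(method, n_estimators = 40, seed = 5))
    expect_lte(cv$summary$r2, 0.1)
  }
})

test_that("ensembles recover strong signal, are seed-deterministic, and importance is a unit mass on true genes", {
  co <- simulate_cohort(quick_config(seed = 43, n_samples = 150))
  e <- preprocess_cohort(co, batch_correct = FALSE)
  truth <- true_genes(co)
  # true genes plus null genes as input features
  feat <- c(truth, setdiff(e$gene_id, truth)[1:40])
  es <- e[e$gene_id %in% feat, ]
  for (method in c("adaptive_boosting", "gradient_boosting",
                   "random_forest")) {
    cv <- fit_predict_cv(es, co$meta,
                         model_spec(method, n_estimators = 60, seed = 11))
    expect_gt(cv$summary$r2, 0.7)
    expect_true(all(cv$importance$importance >= 0))
    expect_equal(sum(cv$importance$importance), 1, tolerance = 1e-9)
    mass <- sum(cv$importance$importance[cv$importance$gene_id %in% truth])
    expect_gt(mass, 0.5)

    cv2 <- fit_predict_cv(es, co$meta,
                          model_spec(method, n_estimators = 60, seed = 11))
    expect_identical(cv$predictions, cv2$predictions)
    expect_identical(cv$importance, cv2$importance)
  }
  expect_error(
    fit_predict_cv(es[, 1:4], co$meta[1:3, ],
                   model_spec("random_forest"), k = 5),
    "fewer samples|fall into")
})

test_that("tidiers expose fold metrics and fit summaries", {
  ages <- round(runif(30, 20, 99))
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:30), age = ages)
  expr <- sncclock:::matrix_to_expr(matrix(
    rbind(ages + rnorm(30), rnorm(30)), 2, 30,
    dimnames = list(c("g1", "g2"), meta$sample_id)))
  cv <- fit_predict_cv(expr, meta, model_spec("random_forest",
                                              n_estimators = 20, seed = 2))
  td <- tidy(cv)
  expect_identical(nrow(td), 5L)
  expect_named(td, c("fold", "r2", "rmse", "mae"))
  gl <- glance(cv)
  expect_identical(gl$method, "random_forest")
  expect_identical(gl$n_genes, 2L)
  expect_identical(nrow(tidy(cv$model)), 2L)
})

test_that("gender-agnostic signal transfers across genders; gender-specific signal does not", {
  # agnostic cohort: male->female performance ~ mixed performance
  co <- simulate_cohort(quick_config(seed = 47, n_samples = 200,
                                     n_batches = 1))
  e <- preprocess_cohort(co, batch_correct = FALSE)
  es <- e[e$gene_id %in% true_genes(co), ]
  spec <- model_spec("gradient_boosting", n_estimators = 60, seed = 13)
  mixed <- fit_predict_cv(es, co$meta, spec)
  xg <- cross_gender_eval(es, co$meta, spec)
  expect_true(all(abs(xg$metrics$r2 - mixed$summary$r2) < 0.1))
  expect_gte(mixed$summary$r2, max(xg$metrics$r2) - 0.02)

  # male-only effects: training on males cannot predict females
  co_m <- simulate_cohort(quick_config(seed = 48, n_samples = 200,
                                       n_batches = 1,
                                       frac_gender_specific = 1))
  tg <- co_m$truth$genes
  male_genes <- tg$gene_id[tg$age_linked & tg$gender_specific == "male"]
  e_m <- preprocess_cohort(co_m, batch_correct = FALSE)
  es_m <- e_m[e_m$gene_id %in% male_genes, ]
  mixed_m <- fit_predict_cv(es_m, co_m$meta, spec)
  xg_m <- cross_gender_eval(es_m, co_m$meta, spec)
  m2f <- xg_m$metrics$r2[xg_m$metrics$direction == "male_to_female"]
  expect_gt(mixed_m$summary$r2 - m2f, 0.1)

  xg_m2 <- cross_gender_eval(es_m, co_m$meta, spec)
  expect_identical(xg_m$metrics, xg_m2$metrics)

  meta_single <- co$meta
  meta_single$gender <- "male"
  expect_error(cross_gender_eval(es, meta_single, spec), "both genders")
})
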