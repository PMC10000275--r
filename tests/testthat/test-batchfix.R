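sim_batch_matrix <- function(G = 200, n = 60, shift_sd = 1, noise = 0.5,
                             seed = 21) {
  set.seed(seed)
  batch <- rep(c("A", "B"), each = n / 2)
  Y <- matrix(rnorm(G * n, 6, noise), G, n) +
    outer(rnorm(G, 0, shift_sd), as.numeric(batch == "B"))
  dimnames(Y) <- list(sprintf("g%03d", 1:G), sprintf("S%03d", 1:n))
  list(expr = sncclock:::matrix_to_expr(Y), batch = batch, Y = Y)
}

test_that("single batches, singleton batches and flat genes are handled", {
  d <- sim_batch_matrix()
  expect_message(res <- combat_correct(d$expr, rep("A", length(d$batch))),
                 "single batch")
  expect_identical(res$expr, d$expr)
  expect_null(res$model)

  expect_error(combat_correct(d$expr, c("A", rep("B", length(d$batch) - 1))),
               "single sample")

  Yz <- d$Y
  Yz[1, ] <- 3 # zero variance
  expect_warning(
    rz <- combat_correct(sncclock:::matrix_to_expr(Yz), d$batch,
                         scale = "raw"),
    "zero-variance")
  expect_equal(as.numeric(rz$expr[1, -1]), Yz[1, ], ignore_attr = TRUE)
})

test_that("an injected constant batch shift is essentially removed", {
  set.seed(22)
  G <- 500; n <- 60
  batch <- rep(c("A", "B"), each = n / 2)
  Y <- matrix(rnorm(G * n, 5, 1), G, n)
  Y[, batch == "B"] <- Y[, batch == "B"] + 2
  dimnames(Y) <- list(sprintf("g%03d", 1:G), sprintf("S%03d", 1:n))
  res <- combat_correct(sncclock:::matrix_to_expr(Y), batch, scale = "raw")
  Yc <- sncclock:::expr_to_matrix(res$expr)
  pre <- rowMeans(Y[, batch == "A"]) - rowMeans(Y[, batch == "B"])
  post <- rowMeans(Yc[, batch == "A"]) - rowMeans(Yc[, batch == "B"])
  # the common 2.0 offset goes into the batch-level prior and is removed;
  # what remains is (shrunken) per-gene sampling noise
  expect_lt(mean(abs(post)), mean(abs(pre)) / 10)
  expect_lt(abs(mean(post)), 0.02)
})

test_that("correction agrees with the independent reference implementation", {
  inp <- read_expr_tsv(test_path("fixtures", "combat_input.tsv"))
  batch <- readLines(test_path("fixtures", "combat_batch.txt"))
  expected <- sncclock:::expr_to_matrix(
    read_expr_tsv(test_path("fixtures", "combat_expected.tsv")))
  got <- sncclock:::expr_to_matrix(
    combat_correct(inp, batch, scale = "raw")$expr)
  expect_lt(max(abs(got - expected)), 1e-4)
})

test_that("grand means are preserved and repeated correction moves little", {
  d <- sim_batch_matrix(G = 300, n = 100, shift_sd = 1, noise = 0.5)
  res <- combat_correct(d$expr, d$batch, scale = "raw")
  Yc <- sncclock:::expr_to_matrix(res$expr)
  # location effects are redistributed, not removed globally
  expect_lt(max(abs(rowMeans(Yc) - rowMeans(d$Y))), 0.05)

  res2 <- combat_correct(res$expr, d$batch, scale = "raw")
  first <- max(abs(Yc - d$Y))
  second <- max(abs(sncclock:::expr_to_matrix(res2$expr) - Yc))
  # the EB prior always re-shrinks residual sampling noise, so exact
  # idempotence is unattainable; a second pass must be a small fraction
  # of the first
  expect_lt(second, 0.05 * first)
})

test_that("protected covariate signal survives correction", {
  set.seed(23)
  G <- 200; n <- 120
  batch <- rep(c("A", "B"), each = n / 2)
  age <- round(runif(n, 20, 99))
  slope <- c(rep(0.05, 20), rep(0, G - 20)) # strong-effect genes first
  Y <- matrix(rnorm(G * n, 5, 0.5), G, n) +
    outer(rnorm(G, 0, 1), as.numeric(batch == "B")) +
    outer(slope, age - mean(age))
  dimnames(Y) <- list(sprintf("g%03d", 1:G), sprintf("S%03d", 1:n))
  res <- combat_correct(sncclock:::matrix_to_expr(Y), batch,
                        covariates = data.frame(age = age), scale = "raw")
  Yc <- sncclock:::expr_to_matrix(res$expr)
  rec <- apply(Yc[1:20, ], 1, function(yg) coef(lm(yg ~ age))[2])
  expect_true(all(abs(rec - 0.05) < 0.2 * 0.05))
})

test_that("the PC diagnostic quantifies batch structure before and after correction", {
  d <- sim_batch_matrix(G = 300, n = 80, shift_sd = 2, noise = 0.5,
                        seed = 25)
  meta <- tibble::tibble(sample_id = colnames(d$Y), batch = d$batch,
                         age = round(runif(80, 20, 99)))
  before <- pca_diagnostic(d$expr, meta, log = FALSE)
  expect_gt(batch_r2(before), 0.5)

  res <- combat_correct(d$expr, d$batch, scale = "raw")
  after <- pca_diagnostic(res$expr, meta, log = FALSE)
  expect_lt(batch_r2(after), 0.1)

  # identical samples: degenerate decomposition is reported, not an error
  flat <- sncclock:::matrix_to_expr(
    matrix(5, 20, 4, dimnames = list(paste0("g", 1:20), paste0("S", 1:4))))
  meta_f <- tibble::tibble(sample_id = paste0("S", 1:4),
                           batch = c("A", "A", "B", "B"), age = 30:33)
  deg <- pca_diagnostic(flat, meta_f, log = FALSE)
  expect_true(attr(deg, "degenerate"))
  expect_true(all(deg$PC1 == 0))
})
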