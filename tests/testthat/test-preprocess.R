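make_meta <- function(transcriptome, total) {
  tibble::tibble(sample_id = sprintf("S%d", seq_along(transcriptome)),
                 transcriptome_reads = transcriptome, total_reads = total)
}

test_that("qc_filter applies the read-count and ratio thresholds with printed inclusivity", {
  meta <- make_meta(
    transcriptome = c(100000, 99999, 200000, 150000),
    total = c(100000 / 0.6, 120000, 400000, 200000)
  )
  res <- qc_filter(meta)
  # 100,000 reads at ratio 0.6: the minimum is inclusive
  expect_true("S1" %in% res$retained)
  # one read short fails
  expect_false("S2" %in% res$retained)
  expect_identical(res$audit$failed_rule[2], "reads")
  # ratio exactly 0.5 fails: "more than 0.5" is strict
  expect_false("S3" %in% res$retained)
  expect_identical(res$audit$failed_rule[3], "ratio")
  expect_true("S4" %in% res$retained)

  bad <- make_meta(c(1e5, NA), c(2e5, 2e5))
  expect_error(qc_filter(bad), "S2")
})

test_that("TMM factors match the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  m <- matrix(rnbinom(1500 * 10, mu = 40 * exp(rnorm(1500)), size = 4),
              nrow = 1500,
              dimnames = list(sprintf("g%04d", 1:1500), sprintf("S%02d", 1:10)))
  f <- tmm_factors(sncclock:::matrix_to_expr(m))
  fe <- edgeR::calcNormFactors(m, method = "TMM")
  expect_lt(max(abs(f - fe)), 1e-6)

  # identical samples: unit factors
  mi <- matrix(rep(m[, 1], 4), ncol = 4,
               dimnames = list(rownames(m), paste0("T", 1:4)))
  expect_true(all(tmm_factors(sncclock:::matrix_to_expr(mi)) == 1))

  # pure depth change is absorbed by the library size, not the factor
  m2 <- cbind(A = m[, 1], B = m[, 1] * 3L)
  f2 <- tmm_factors(sncclock:::matrix_to_expr(m2))
  fe2 <- edgeR::calcNormFactors(m2, method = "TMM")
  expect_lt(max(abs(f2 - 1)), 1e-6)
  expect_lt(max(abs(f2 - fe2)), 1e-6)

  # no shared positive genes
  m3 <- matrix(c(5, 0, 0, 7), 2, dimnames = list(c("a", "b"), c("X", "Y")))
  expect_error(tmm_factors(sncclock:::matrix_to_expr(m3)), "no positive genes")
})

test_that("cpm_normalize scales counts per million of normalized library size", {
  m <- matrix(c(10, 90, 30, 70), nrow = 2,
              dimnames = list(c("g1", "g2"), c("S1", "S2")))
  e <- cpm_normalize(sncclock:::matrix_to_expr(m))
  expect_equal(unname(colSums(sncclock:::expr_to_matrix(e))), c(1e6, 1e6))

  one <- sncclock:::matrix_to_expr(
    matrix(50, 1, 1, dimnames = list("g1", "S1")))
  expect_equal(
    as.numeric(cpm_normalize(one, lib_size = 1e6)[, -1]), 50)

  e1 <- cpm_normalize(sncclock:::matrix_to_expr(m),
                      factors = c(S1 = 1, S2 = 1))
  e2 <- cpm_normalize(sncclock:::matrix_to_expr(m),
                      factors = c(S1 = 1, S2 = 2))
  expect_equal(as.numeric(e2$S2), as.numeric(e1$S2) / 2)
  expect_equal(as.numeric(e2$S1), as.numeric(e1$S1))
})

test_that("detection filter is existential over age groups, monotone and nested", {
  n_per <- c(young = 10, adult = 10, aged = 10)
  ages <- c(rep(25, 10), rep(45, 10), rep(70, 10))
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:30), age = ages)
  m <- matrix(0, 4, 30, dimnames = list(paste0("g", 1:4), meta$sample_id))
  m[1, ] <- 12                 # everywhere high
  m[2, ] <- 5                  # everywhere moderate
  m[3, 1:3] <- 11              # 3/10 of the young group
  m[4, 1] <- 11                # 1/10 of the young group
  e <- sncclock:::matrix_to_expr(m)

  kept10 <- detection_filter(e, meta, rule = detection_rule(min_cpm = 10))
  expect_setequal(kept10, c("g1", "g3"))   # 3/10 >= 0.30 qualifies
  kept1 <- detection_filter(e, meta, rule = detection_rule(min_cpm = 1))
  expect_true(all(kept10 %in% kept1))      # expressed ⊇ highly expressed
  expect_true("g2" %in% kept1)

  # monotone: raising min_cpm or min_fraction never adds genes
  for (cpm_hi in c(2, 10, 20)) {
    expect_true(all(
      detection_filter(e, meta, rule = detection_rule(min_cpm = cpm_hi)) %in%
        detection_filter(e, meta, rule = detection_rule(min_cpm = 1))))
  }
  expect_true(all(
    detection_filter(e, meta,
                     rule = detection_rule(10, min_fraction = 0.5)) %in%
      kept10))

  # all-groups scope is stricter
  expect_setequal(
    detection_filter(e, meta,
                     rule = detection_rule(10, scope = "all_groups")),
    "g1")

  # an empty age group warns and cannot qualify genes
  meta_young <- meta[1:10, ]
  expect_warning(
    detection_filter(e[, c("gene_id", meta_young$sample_id)], meta_young,
                     rule = detection_rule(10)),
    "empty age group")
})

test_that("composition summary yields per-group shares that sum to one", {
  ages <- c(rep(25, 6), rep(70, 6))
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:12), age = ages)
  m <- matrix(20, 2, 12, dimnames = list(c("g1", "g2"), meta$sample_id))
  e <- sncclock:::matrix_to_expr(m)
  bio1 <- tibble::tibble(gene_id = c("g1", "g2"), biotype = "miRNA")
  cs <- composition_summary(e, bio1, meta)
  expect_true(all(cs$gene_share == 1))
  expect_true(all(cs$cpm_share == 1))

  bio2 <- tibble::tibble(gene_id = c("g1", "g2"),
                         biotype = c("miRNA", "tRNA"))
  cs2 <- composition_summary(e, bio2, meta)
  expect_true(all(abs(cs2$cpm_share - 0.5) < 1e-12))

  sums <- cs2 |>
    dplyr::group_by(age_group) |>
    dplyr::summarise(g = sum(gene_share), c = sum(cpm_share))
  expect_true(all(abs(sums$g - 1) < 1e-12))
  expect_true(all(abs(sums$c - 1) < 1e-12))
})

test_that("simulated composition trend appears in the highly expressed summary", {
  co <- simulate_cohort(sim_config(n_samples = 300, seed = 17))
  e <- cpm_normalize(co$counts, tmm_factors(co$counts))
  cs <- composition_summary(e, co$truth$genes, co$meta)
  mi <- cs[cs$biotype == "miRNA", ]
  expect_lt(mi$cpm_share[mi$age_group == "aged"],
            mi$cpm_share[mi$age_group == "young"])
})
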