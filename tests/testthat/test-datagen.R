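test_that("generation is deterministic and degenerate settings behave", {
  cfg <- quick_config(seed = 3, frac_age_linked = 0)
  co <- simulate_cohort(cfg)
  expect_false(any(co$truth$genes$age_linked))
  expect_true(all(co$truth$genes$effect_size == 0))

  co2 <- simulate_cohort(cfg)
  expect_identical(co, co2)

  cfg2 <- quick_config(seed = 4, frac_age_linked = 0.1)
  tg <- simulate_cohort(cfg2)$truth$genes
  expect_true(all(tg$effect_size[tg$age_linked] != 0))
  expect_identical(nrow(tg), as.integer(sum(quick_config()$biotype_counts)))

  expect_error(sim_config(n_samples = 0), "at least one sample")
  expect_error(quick_config(biotype_counts = c(miRNA = 0, tRNA = 0)),
               "at least one gene")
})

test_that("counts are non-negative integers with library sizes near the configured log-normal", {
  co <- simulate_cohort(quick_config(seed = 5))
  m <- sncclock:::expr_to_matrix(co$counts)
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  # per-sample totals track the drawn library sizes within stochastic range
  ratio <- colSums(m) / co$truth$samples$true_libsize
  expect_true(all(ratio > 0.5 & ratio < 2))
  expect_true(all(co$meta$transcriptome_reads / co$meta$total_reads <= 0.81))
})

test_that("a single strong linear gene's log-CPM tracks age", {
  # near-Poisson counts, one batch: the linear effect should dominate
  cfg <- quick_config(
    seed = 6, n_samples = 500,
    biotype_counts = c(miRNA = 30), frac_age_linked = 1 / 30,
    relationship_mix = c(linear = 1), effect_size_sd = 1.0,
    dispersion = 1e-9, n_batches = 1
  )
  co <- simulate_cohort(cfg)
  g <- true_genes(co)
  expect_length(g, 1)
  e <- cpm_normalize(co$counts)
  x <- log1p(as.numeric(e[e$gene_id == g, -1]))
  eff <- co$truth$genes$effect_size[co$truth$genes$gene_id == g]
  expect_gt(abs(cor(x, co$meta$age)), 0.9)
  expect_equal(sign(cor(x, co$meta$age)), sign(eff))
})

test_that("qc failure injection corrupts exactly the requested fraction", {
  co <- simulate_cohort(quick_config(seed = 7, n_samples = 100))
  m0 <- inject_qc_failures(co$meta, 0)
  expect_identical(m0$transcriptome_reads, co$meta$transcriptome_reads)
  expect_false(any(m0$qc_injected))

  m1 <- inject_qc_failures(co$meta, 1, seed = 2)
  expect_length(qc_filter(m1)$retained, 0)

  m25 <- inject_qc_failures(co$meta, 0.25, seed = 3)
  # brute-force application of the QC predicate
  fails <- !(m25$transcriptome_reads >= 1e5 &
               m25$transcriptome_reads / m25$total_reads > 0.5)
  expect_identical(sum(fails), 25L)
  expect_identical(which(fails), which(m25$qc_injected))
})

test_that("composition trend lowers miRNA and raises tRNA share with age", {
  co <- simulate_cohort(sim_config(n_samples = 300, seed = 11))
  e <- cpm_normalize(co$counts, tmm_factors(co$counts))
  m <- sncclock:::expr_to_matrix(e)
  bio <- co$truth$genes$biotype
  grp <- assign_age_group(co$meta$age)
  share <- function(b, g) {
    sub <- m[bio == b, grp == g, drop = FALSE]
    sum(sub) / sum(m[, grp == g])
  }
  expect_lt(share("miRNA", "aged"), share("miRNA", "young"))
  expect_gt(share("tRNA", "aged"), share("tRNA", "young"))
})

test_that("null genes are exchangeable across age groups at the nominal test level", {
  co <- simulate_cohort(quick_config(
    seed = 13, n_samples = 150, frac_age_linked = 0, n_batches = 1,
    composition_trend = FALSE
  ))
  e <- cpm_normalize(co$counts)
  m <- sncclock:::expr_to_matrix(e)
  grp <- assign_age_group(co$meta$age)
  pvals <- apply(m[seq_len(200), ], 1, function(x) {
    stats::kruskal.test(x, grp)$p.value
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("cohort artifacts round-trip through the writers", {
  co <- simulate_cohort(quick_config(seed = 15, n_samples = 20,
                                     biotype_counts = c(miRNA = 25)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, mtx = TRUE)
  counts2 <- read_expr_tsv(file.path(dir, "counts.tsv"))
  expect_equal(as.data.frame(counts2), as.data.frame(co$counts))
  mtx <- read_counts_mtx(file.path(dir, "counts.mtx"))
  expect_equal(sncclock:::expr_to_matrix(mtx),
               sncclock:::expr_to_matrix(co$counts))
  meta2 <- read_table_tsv(file.path(dir, "meta.tsv"))
  expect_equal(meta2$age, co$meta$age)
})
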