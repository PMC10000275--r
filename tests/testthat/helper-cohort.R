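# Small cohort configurations shared across test files.

quick_config <- function(seed = 1L, n_samples = 120, ...) {
  args <- list(
    n_samples = n_samples,
    biotype_counts = c(miRNA = 90, tRNA = 30, piRNA = 40, snRNA = 20,
                       snoRNA = 15, scRNA = 5),
    frac_age_linked = 0.1,
    effect_size_sd = 1.5,
    dispersion = 0.05,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# cohort -> corrected expression of expressed genes (the screen's input)
preprocess_cohort <- function(cohort, batch_correct = TRUE) {
  f <- tmm_factors(cohort$counts)
  e <- cpm_normalize(cohort$counts, f)
  e <- e[e$gene_id %in% detection_filter(e, cohort$meta), ]
  if (batch_correct && length(unique(cohort$meta$batch)) > 1) {
    e <- combat_correct(e, cohort$meta$batch)$expr
  }
  e
}

true_genes <- function(cohort) {
  cohort$truth$genes$gene_id[cohort$truth$genes$age_linked]
}
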