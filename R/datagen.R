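# Synthetic exRNA cohort generator. Produces gene x sample negative-
# binomial counts whose log-scale structure (per-gene baselines, smooth or
# step age effects, additive batch location shifts, multiplicative batch
# scaling of residual noise) mirrors what the downstream normalization,
# batch-correction and screening stages assume, with full ground truth so
# sensitivity/specificity can be measured exactly.

SNC_BIOTYPES <- c("miRNA", "tRNA", "piRNA", "snRNA", "snoRNA", "scRNA")
SNC_RELATIONSHIPS <- c("linear", "saturating", "quadratic", "step")

#' Simulation configuration for a synthetic exRNA cohort
#'
#' Defaults describe a cohort of 300 donors aged 20--99 profiled across
#' three batches, with 1000 sncRNA genes across six biotypes of which 4%
#' carry an age effect. Age effects act on the natural-log expression scale
#' as a function of standardized age \eqn{z = (age - 59.5)/22.9}.
#'
#' @param n_samples Number of donors.
#' @param age_min,age_max Age range in years (uniform sampling).
#' @param gender_balance Fraction of male donors.
#' @param n_batches Number of batches (studies/library preparations).
#' @param batch_shift_sd SD of the per-gene-per-batch additive location
#'   effect on the natural-log scale.
#' @param batch_scale_range Length-2 interval; each batch draws a
#'   multiplicative factor for residual log-noise from it.
#' @param biotype_counts Named integer vector, genes per biotype; names
#'   must come from `r paste(SNC_BIOTYPES, collapse = ", ")`.
#' @param frac_age_linked Fraction of genes with an age effect.
#' @param relationship_mix Named proportions over
#'   linear/saturating/quadratic/step age-response shapes.
#' @param effect_size_sd Scale of per-gene effect sizes: natural-log
#'   expression change per unit standardized age. Magnitudes are drawn
#'   around this scale (never at zero) with a random sign.
#' @param frac_gender_specific Fraction of age-linked genes whose effect
#'   applies to one gender only.
#' @param libsize_log_mean,libsize_log_sd Log-normal parameters of the true
#'   (transcriptome-aligned) library size.
#' @param dispersion Negative-binomial dispersion (1/size); values below
#'   1e-8 fall back to Poisson sampling.
#' @param noise_sd SD of residual per-observation log-noise before batch
#'   scaling.
#' @param composition_trend If `TRUE`, miRNA baselines drift down and tRNA
#'   baselines up with standardized age, reproducing the aggregate
#'   miRNA-down / tRNA-up composition shift seen in circulating sncRNA.
#' @param transcriptome_frac Transcriptome reads as a fraction of total
#'   reads recorded in the metadata.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 300,
                       age_min = 20, age_max = 99,
                       gender_balance = 0.5,
                       n_batches = 3,
                       batch_shift_sd = 0.5,
                       batch_scale_range = c(0.5, 2),
                       biotype_counts = c(miRNA = 450, tRNA = 150,
                                          piRNA = 200, snRNA = 100,
                                          snoRNA = 80, scRNA = 20),
                       frac_age_linked = 0.04,
                       relationship_mix = c(linear = 0.5, saturating = 0.2,
                                            quadratic = 0.2, step = 0.1),
                       effect_size_sd = 1.0,
                       frac_gender_specific = 0,
                       libsize_log_mean = log(2e6),
                       libsize_log_sd = 0.4,
                       dispersion = 0.2,
                       noise_sd = 0.3,
                       composition_trend = TRUE,
                       transcriptome_frac = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), age_min = age_min, age_max = age_max,
    gender_balance = gender_balance, n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, batch_scale_range = batch_scale_range,
    biotype_counts = biotype_counts, frac_age_linked = frac_age_linked,
    relationship_mix = relationship_mix, effect_size_sd = effect_size_sd,
    frac_gender_specific = frac_gender_specific,
    libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
    dispersion = dispersion, noise_sd = noise_sd,
    composition_trend = isTRUE(composition_trend),
    transcriptome_frac = transcriptome_frac, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("gender_balance", "frac_age_linked", "frac_gender_specific",
              "transcriptome_frac")) {
    check_scalar_fraction(cfg[[f]], f)
  }
  if (cfg$age_min >= cfg$age_max) abort("age_min must be < age_max")
  if (cfg$n_samples < 1) abort("cohort must contain at least one sample")
  if (!all(names(cfg$biotype_counts) %in% SNC_BIOTYPES)) {
    abort(paste0("biotype names must be among: ",
                 paste(SNC_BIOTYPES, collapse = ", ")))
  }
  if (any(cfg$biotype_counts < 0)) abort("biotype_counts must be >= 0")
  if (sum(cfg$biotype_counts) < 1) abort("cohort must contain at least one gene")
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (!all(names(cfg$relationship_mix) %in% SNC_RELATIONSHIPS)) {
    abort(paste0("relationship names must be among: ",
                 paste(SNC_RELATIONSHIPS, collapse = ", ")))
  }
  if (abs(sum(cfg$relationship_mix) - 1) > 1e-8) {
    abort("relationship_mix must sum to 1")
  }
  if (length(cfg$batch_scale_range) != 2 ||
      cfg$batch_scale_range[1] <= 0 ||
      diff(cfg$batch_scale_range) < 0) {
    abort("batch_scale_range must be a positive increasing interval")
  }
  invisible(cfg)
}

# standardized age: centred at the cohort midpoint, scaled by the SD of a
# uniform age distribution over [20, 99] (~22.9 years), so effect sizes are
# comparable across relationship shapes
standardize_age <- function(age) (age - 59.5) / 22.9

age_response <- function(relationship, z) {
  switch(relationship,
    linear = z,
    saturating = tanh(z),
    # centred so the linear correlation with age is ~0 while the
    # association is strong; exercises the MIC-vs-Pearson distinction
    quadratic = z^2 - mean(z^2),
    step = (z > 0) - 0.5,
    abort(paste0("unknown relationship: ", relationship))
  )
}

#' Simulate a synthetic exRNA cohort with known ground truth
#'
#' Counts for gene g in sample s are negative binomial with mean
#' `libsize_s * p_gs`, where `p_gs` is the per-sample softmax of the
#' natural-log expression score: gene baseline + age response (for
#' age-linked genes, possibly gender-restricted) + batch location shift +
#' batch-scaled residual noise. The softmax induces the compositional
#' coupling CPM data has.
#'
#' @param config A [sim_config()].
#' @return An object of class `snc_cohort`: a list with `counts` (tibble,
#'   `gene_id` + one column per sample), `meta` (per-sample tibble with
#'   `sample_id`, `age`, `gender`, `biofluid`, `batch`, `total_reads`,
#'   `transcriptome_reads`), and `truth` (list of `genes` and `samples`
#'   tibbles recording every simulated effect).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    G <- sum(config$biotype_counts)
    biotype <- rep(names(config$biotype_counts), config$biotype_counts)
    gene_id <- sprintf("%s-g%04d", biotype, seq_len(G))

    # samples
    age <- round(runif(n, config$age_min, config$age_max))
    gender <- ifelse(runif(n) < config$gender_balance, "male", "female")
    biofluid <- ifelse(runif(n) < 302 / 446, "plasma", "serum")
    batch <- paste0("batch", sample.int(config$n_batches, n, replace = TRUE))
    libsize <- rlnorm_clamped(n, config$libsize_log_mean, config$libsize_log_sd)
    sample_id <- sprintf("S%03d", seq_len(n))
    z <- standardize_age(age)

    # gene truth
    n_linked <- round(config$frac_age_linked * G)
    linked <- sort(sample.int(G, n_linked))
    age_linked <- seq_len(G) %in% linked
    relationship <- rep(NA_character_, G)
    if (n_linked > 0) {
      relationship[linked] <- sample(names(config$relationship_mix), n_linked,
                                     replace = TRUE,
                                     prob = config$relationship_mix)
    }
    # effect magnitudes concentrate around effect_size_sd (floored away from
    # zero so "age-linked" always means a detectable direction of effect)
    effect_size <- rep(0, G)
    if (n_linked > 0) {
      mag <- abs(rnorm(n_linked, mean = config$effect_size_sd,
                       sd = config$effect_size_sd / 3))
      mag <- pmax(mag, 0.1 * config$effect_size_sd)
      effect_size[linked] <- mag * sample(c(-1, 1), n_linked, replace = TRUE)
    }
    gender_specific <- rep("none", G)
    if (n_linked > 0 && config$frac_gender_specific > 0) {
      n_gs <- round(config$frac_gender_specific * n_linked)
      pick <- sample(linked, n_gs)
      gender_specific[pick] <- sample(c("male", "female"), n_gs, replace = TRUE)
    }

    # per-biotype baseline offsets give miRNA (and to a degree tRNA) the
    # dominant abundance share typical of circulating small RNA
    base_offset <- c(miRNA = 1.0, tRNA = 0.5, piRNA = 0, snRNA = 0,
                     snoRNA = 0, scRNA = -0.5)[biotype]
    baseline <- rnorm(G, 0, 1.5) + base_offset

    # log-expression score eta: genes x samples
    eta <- matrix(baseline, nrow = G, ncol = n)
    for (g in linked) {
      fg <- effect_size[g] * age_response(relationship[g], z)
      if (gender_specific[g] != "none") {
        fg <- fg * (gender == gender_specific[g])
      }
      eta[g, ] <- eta[g, ] + fg
    }
    if (config$composition_trend) {
      trend <- 0.25
      drift <- function(sgn, b) {
        nb <- sum(biotype == b)
        if (nb == 0) return()
        eta[biotype == b, ] <<- eta[biotype == b, , drop = FALSE] +
          matrix(sgn * trend * z, nrow = nb, ncol = n, byrow = TRUE)
      }
      drift(-1, "miRNA")
      drift(+1, "tRNA")
    }
    batch_shift <- matrix(rnorm(G * config$n_batches, 0,
                                config$batch_shift_sd),
                          nrow = G, ncol = config$n_batches)
    batch_scale <- runif(config$n_batches, config$batch_scale_range[1],
                         config$batch_scale_range[2])
    if (config$n_batches == 1) {
      batch_shift[] <- 0
      batch_scale[] <- 1
    }
    bidx <- as.integer(sub("batch", "", batch))
    eta <- eta + batch_shift[, bidx, drop = FALSE]
    noise <- matrix(rnorm(G * n, 0, config$noise_sd), nrow = G, ncol = n)
    eta <- eta + sweep(noise, 2, batch_scale[bidx], `*`)

    # softmax per sample -> expected proportions, then NB counts
    p <- apply(eta, 2, function(col) {
      e <- exp(col - max(col))
      e / sum(e)
    })
    mu <- sweep(p, 2, libsize, `*`)
    counts <- if (config$dispersion < 1e-8) {
      matrix(rpois(G * n, lambda = mu), nrow = G)
    } else {
      matrix(rnbinom(G * n, mu = mu, size = 1 / config$dispersion), nrow = G)
    }
    dimnames(counts) <- list(gene_id, sample_id)

    meta <- tibble::tibble(
      sample_id = sample_id, age = age, gender = gender,
      biofluid = biofluid, batch = batch,
      transcriptome_reads = round(libsize),
      total_reads = round(libsize / config$transcriptome_frac)
    )
    truth <- list(
      genes = tibble::tibble(
        gene_id = gene_id, biotype = biotype, age_linked = age_linked,
        relationship = relationship, effect_size = effect_size,
        gender_specific = gender_specific
      ),
      samples = tibble::tibble(
        sample_id = sample_id, age = age, gender = gender, batch = batch,
        true_libsize = libsize
      )
    )
    structure(
      list(counts = matrix_to_expr(counts), meta = meta, truth = truth,
           config = config),
      class = "snc_cohort"
    )
  })
}

rlnorm_clamped <- function(n, meanlog, sdlog) {
  pmax(stats::rlnorm(n, meanlog, sdlog), 1)
}

#' @export
print.snc_cohort <- function(x, ...) {
  cat("<snc_cohort> ", nrow(x$counts), " genes x ", nrow(x$meta),
      " samples, ", sum(x$truth$genes$age_linked), " age-linked genes\n",
      sep = "")
  invisible(x)
}

#' Inject sample-level QC failures into cohort metadata
#'
#' A random `ceiling(fraction * n)` subset of samples is altered so that it
#' violates the ERCC-style quality thresholds: either the transcriptome
#' read count is dropped below 100,000 or the transcriptome/total read
#' ratio is pushed to 0.5 or below. The altered samples are flagged in the
#' `qc_injected` audit column.
#'
#' @param meta Sample metadata tibble (as from [simulate_cohort()]).
#' @param fraction Fraction of samples to corrupt, in \[0, 1\].
#' @param seed Integer seed.
#' @return `meta` with `qc_injected` (logical) and `qc_injected_mode`
#'   (`"low_reads"`, `"low_ratio"`, or `NA`) columns appended.
#' @export
inject_qc_failures <- function(meta, fraction, seed = 1L) {
  check_scalar_fraction(fraction, "fraction")
  n <- nrow(meta)
  out <- meta
  out$qc_injected <- FALSE
  out$qc_injected_mode <- NA_character_
  n_fail <- ceiling(fraction * n)
  if (n_fail == 0) return(out)
  with_seed(seed, {
    idx <- sample.int(n, n_fail)
    mode <- sample(c("low_reads", "low_ratio"), n_fail, replace = TRUE)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (mode[j] == "low_reads") {
        out$transcriptome_reads[i] <- sample(10000:99999, 1)
        out$total_reads[i] <- max(out$total_reads[i],
                                  out$transcriptome_reads[i] * 2 + 1)
        # ratio may or may not pass; the read count alone already fails
      } else {
        target <- runif(1, 0.3, 0.5)
        out$total_reads[i] <- ceiling(out$transcriptome_reads[i] / target)
      }
    }
    out$qc_injected[idx] <- TRUE
    out$qc_injected_mode[idx] <- mode
  })
  out
}

#' Write cohort artifacts as tab-delimited text
#'
#' @param cohort An `snc_cohort`.
#' @param dir Output directory (created if absent).
#' @param mtx Also write counts in sparse triplet form.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, mtx = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expr_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_table_tsv(cohort$meta, file.path(dir, "meta.tsv"))
  write_table_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_table_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"))
  if (mtx) write_counts_mtx(cohort$counts, file.path(dir, "counts.mtx"))
  invisible(dir)
}

#' Committed strong-signal cohort configuration
#'
#' The reference end-to-end recovery setting used throughout the tests:
#' 300 donors, 1000 genes of which 40 carry strong age effects
#' (`effect_size_sd = 1.5` natural-log units per standardized age) at low
#' counting noise (`dispersion = 0.05`), two batches with moderate
#' location/scale effects.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
strong_signal_config <- function(seed = 101L) {
  sim_config(
    n_samples = 300,
    n_batches = 2,
    batch_shift_sd = 0.4,
    batch_scale_range = c(0.8, 1.25),
    frac_age_linked = 0.04,
    effect_size_sd = 1.5,
    dispersion = 0.05,
    seed = seed
  )
}
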