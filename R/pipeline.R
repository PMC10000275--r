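# End-to-end orchestration: simulate/load -> qc -> normalize -> detect ->
# correct -> screen -> clock (per model) -> consensus, with every
# intermediate written as tab-delimited text, a manifest recording seeds,
# parameters and per-stage record counts, and deterministic re-runs.

#' Pipeline configuration
#'
#' Either simulate a cohort (`sim` is a [sim_config()]) or load one from
#' `input_dir` (files as written by [write_cohort()]). The global `seed`
#' fans out to per-stage seeds by fixed offsets so stages are
#' independently reproducible.
#'
#' @param sim A [sim_config()], or `NULL` when loading from files.
#' @param input_dir Directory with `counts.tsv` and `meta.tsv` when `sim`
#'   is `NULL`.
#' @param qc A [qc_thresholds()].
#' @param grouping An [age_grouping()].
#' @param detection A [detection_rule()] defining the expressed set fed to
#'   the screen.
#' @param use_tmm Apply TMM factors to the library sizes before CPM.
#' @param batch_correct Toggle ComBat-style correction.
#' @param protect_age_group Add age group as a protected covariate in the
#'   correction.
#' @param mine A [mine_params()].
#' @param mic_threshold Dual MIC/TIC screen threshold.
#' @param models List of [model_spec()]s to fit; defaults to all five
#'   methods.
#' @param k Cross-validation folds.
#' @param out_dir Output directory for artifacts; `NULL` keeps everything
#'   in memory.
#' @param seed Global integer seed.
#' @param verbose Log stage progress to standard error.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            qc = qc_thresholds(),
                            grouping = age_grouping(),
                            detection = detection_rule(min_cpm = 1),
                            use_tmm = TRUE,
                            batch_correct = TRUE,
                            protect_age_group = FALSE,
                            mine = mine_params(),
                            mic_threshold = 0.7,
                            models = NULL,
                            k = 5,
                            out_dir = NULL,
                            seed = 1L,
                            verbose = TRUE) {
  if (is.null(sim) && is.null(input_dir)) {
    abort("provide either a simulation config or an input directory")
  }
  if (!is.null(input_dir) &&
      !file.exists(file.path(input_dir, "counts.tsv"))) {
    abort(paste0("input_dir lacks counts.tsv: ", input_dir))
  }
  seed <- as.integer(seed)
  models <- models %||% purrr::map(
    CLOCK_METHODS, ~ model_spec(.x, seed = seed + 300L))
  structure(list(sim = sim, input_dir = input_dir, qc = qc,
                 grouping = grouping, detection = detection,
                 use_tmm = use_tmm, batch_correct = batch_correct,
                 protect_age_group = protect_age_group, mine = mine,
                 mic_threshold = mic_threshold, models = models, k = k,
                 out_dir = out_dir, seed = seed, verbose = verbose),
            class = "pipeline_config")
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...)))
  }
}

#' Run the full sncRNA aging-clock pipeline
#'
#' @param config A [pipeline_config()].
#' @return An `snc_run`: `manifest` (stage, status, records in/out,
#'   elapsed seconds), plus every stage result (`cohort`, `qc`, `expr`,
#'   `expressed`, `corrected`, `assoc`, `cv` list, `consensus`).
#'   Re-running with the same config reproduces identical outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_all <- Sys.time()
  manifest <- tibble::tibble(stage = character(), status = character(),
                             n_in = integer(), n_out = integer(),
                             elapsed_s = numeric())
  results <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  record <- function(stage, status, n_in, n_out, t0) {
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, status = status, n_in = as.integer(n_in),
      n_out = as.integer(n_out),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  fail <- function(stage, msg, n_in, t0) {
    record(stage, "FAILED", n_in, 0L, t0)
    if (!is.null(out_dir)) {
      readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
      writeLines(paste0(stage, ": ", msg), file.path(out_dir, "FAILED"))
    }
    abort(paste0("pipeline failed at stage `", stage, "`: ", msg))
  }
  run_stage <- function(stage, n_in, code) {
    t0 <- Sys.time()
    out <- tryCatch(force(code),
                    error = function(e) fail(stage, conditionMessage(e),
                                             n_in, t0))
    record(stage, "PASSED", n_in, attr(out, "n_out") %||% NA_integer_, t0)
    out
  }
  strip <- function(x, n_out) {
    attr(x, "n_out") <- n_out
    x
  }

  # 1. simulate / load
  cohort <- run_stage("simulate", 0L, {
    co <- if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- config$seed + 1L
      simulate_cohort(cfg)
    } else {
      counts <- read_expr_tsv(file.path(config$input_dir, "counts.tsv"))
      meta <- read_table_tsv(file.path(config$input_dir, "meta.tsv"))
      list(counts = counts, meta = meta, truth = NULL)
    }
    stage_log(config$verbose, "simulate", "%d genes x %d samples",
              nrow(co$counts), nrow(co$meta))
    strip(co, nrow(co$meta))
  })
  results$cohort <- cohort

  # 2. qc
  qc <- run_stage("qc", nrow(cohort$meta), {
    q <- qc_filter(cohort$meta, config$qc)
    stage_log(config$verbose, "qc", "%d/%d samples retained",
              length(q$retained), nrow(cohort$meta))
    strip(q, length(q$retained))
  })
  results$qc <- qc
  keep <- c("gene_id", qc$retained)
  counts <- cohort$counts[keep]
  meta <- cohort$meta[cohort$meta$sample_id %in% qc$retained, ]

  # 3. normalize
  expr <- run_stage("normalize", length(qc$retained), {
    if (length(qc$retained) < 2) abort("no samples remain after QC")
    factors <- if (config$use_tmm) tmm_factors(counts) else NULL
    e <- cpm_normalize(counts, factors = factors)
    strip(list(expr = e, factors = factors), ncol(e) - 1L)
  })
  results$expr <- expr$expr
  results$tmm_factors <- expr$factors

  # 4. detection filter (expressed set)
  expressed <- run_stage("detect", nrow(results$expr), {
    g <- detection_filter(results$expr, meta, config$grouping,
                          config$detection)
    if (!length(g)) abort("no genes pass the detection filter")
    stage_log(config$verbose, "detect", "%d expressed genes", length(g))
    strip(g, length(g))
  })
  results$expressed <- expressed
  expr_kept <- results$expr[results$expr$gene_id %in% expressed, ]

  # 5. batch correction
  corrected <- run_stage("correct", nrow(expr_kept), {
    if (!config$batch_correct || length(unique(meta$batch)) < 2) {
      stage_log(config$verbose, "correct", "skipped")
      strip(list(expr = expr_kept, model = NULL), nrow(expr_kept))
    } else {
      cov <- if (config$protect_age_group) {
        data.frame(age_group = assign_age_group(meta$age, config$grouping))
      } else NULL
      cb <- combat_correct(expr_kept, meta$batch, covariates = cov)
      stage_log(config$verbose, "correct", "%d batches adjusted",
                length(unique(meta$batch)))
      strip(cb, nrow(cb$expr))
    }
  })
  results$corrected <- corrected$expr
  results$batch_model <- corrected$model

  # 6. MIC/TIC screen
  assoc <- run_stage("screen", nrow(results$corrected), {
    if (nrow(meta) == 0) abort("no samples remain")
    a <- mic_screen(results$corrected, meta$age,
                    threshold = config$mic_threshold, params = config$mine)
    sel <- sum(a$passes)
    if (sel == 0) abort("no genes pass the MIC/TIC screen")
    stage_log(config$verbose, "screen", "%d age-associated genes", sel)
    strip(a, sel)
  })
  results$assoc <- assoc
  expr_sel <- results$corrected[
    results$corrected$gene_id %in% screen_selected(assoc), ]

  # 7. clock models
  folds <- stratified_age_folds(meta, k = config$k, config$grouping,
                                seed = config$seed + 200L)
  cv <- run_stage("clock", nrow(expr_sel), {
    fits <- purrr::map(config$models, function(sp) {
      fit <- fit_predict_cv(expr_sel, meta, sp, folds = folds)
      stage_log(config$verbose, "clock", "%s R2 = %.3f", sp$method,
                fit$summary$r2)
      fit
    })
    names(fits) <- purrr::map_chr(config$models, "method")
    strip(fits, length(fits))
  })
  results$cv <- cv
  results$folds <- folds

  # 8. consensus
  consensus <- run_stage("consensus", length(cv), {
    tree <- cv[intersect(names(cv), c("adaptive_boosting",
                                      "gradient_boosting",
                                      "random_forest"))]
    if (!length(tree)) {
      strip(tibble::tibble(), 0L)
    } else {
      cons <- rank_sum_core(importance_ranks(collect_importances(tree)))
      stage_log(config$verbose, "consensus", "%d core genes",
                sum(cons$core))
      strip(cons, sum(cons$core))
    }
  })
  results$consensus <- consensus

  run <- structure(list(manifest = manifest, config = config,
                        results = results,
                        elapsed_s = as.numeric(difftime(Sys.time(), t_all,
                                                        units = "secs"))),
                   class = "snc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  r <- run$results
  readr::write_tsv(run$manifest, file.path(out_dir, "manifest.tsv"))
  if (!is.null(r$cohort$truth)) {
    write_cohort(r$cohort, file.path(out_dir, "cohort"))
  }
  write_table_tsv(r$qc$audit, file.path(out_dir, "qc_audit.tsv"))
  write_expr_tsv(r$expr, file.path(out_dir, "cpm.tsv"))
  write_expr_tsv(r$corrected, file.path(out_dir, "corrected.tsv"))
  writeLines(r$expressed, file.path(out_dir, "expressed_genes.txt"))
  write_table_tsv(r$assoc, file.path(out_dir, "association.tsv"))
  metrics <- purrr::imap_dfr(r$cv, function(f, nm) {
    dplyr::bind_cols(tibble::tibble(method = nm), f$summary)
  })
  write_table_tsv(metrics, file.path(out_dir, "clock_metrics.tsv"))
  if (nrow(r$consensus)) {
    bt <- if (!is.null(r$cohort$truth)) r$cohort$truth$genes else NULL
    write_consensus_tsv(r$consensus, file.path(out_dir, "consensus.tsv"),
                        biotypes = bt)
  }
  invisible(out_dir)
}

#' @export
print.snc_run <- function(x, ...) {
  cat("<snc_run> ", nrow(x$manifest), " stages, ",
      sum(x$manifest$status == "PASSED"), " passed (",
      sprintf("%.1f", x$elapsed_s), " s)\n", sep = "")
  print(x$manifest)
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Summarises a run: per-stage record counts, biotype composition of the
#' expressed set, association counts, per-model metrics and the top of the
#' consensus table.
#'
#' @param run An `snc_run` from [run_pipeline()].
#' @param top_n Consensus rows to show.
#' @return Character vector of report lines, invisibly printed.
#' @export
pipeline_report <- function(run, top_n = 10) {
  r <- run$results
  lines <- c("== sncRNA aging-clock pipeline report ==", "",
             "Stages:")
  lines <- c(lines, sprintf("  %-10s %-7s in=%-6s out=%-6s %.2fs",
                            run$manifest$stage, run$manifest$status,
                            run$manifest$n_in, run$manifest$n_out,
                            run$manifest$elapsed_s))
  lines <- c(lines, "",
             sprintf("Expressed genes: %d; screened age-associated: %d",
                     length(r$expressed), sum(r$assoc$passes)))
  if (length(r$cv)) {
    lines <- c(lines, "", "Clock performance (out-of-fold means):")
    for (nm in names(r$cv)) {
      s <- r$cv[[nm]]$summary
      lines <- c(lines, sprintf("  %-18s R2 = %6.3f  RMSE = %6.2f y  MAE = %6.2f y",
                                nm, s$r2, s$rmse, s$mae))
    }
  }
  if (!is.null(r$consensus) && nrow(r$consensus) &&
      any(r$consensus$core)) {
    top <- head(r$consensus[r$consensus$core, ], top_n)
    lines <- c(lines, "", sprintf("Top %d consensus genes (rank sum):",
                                  nrow(top)),
               sprintf("  %-24s %5d", top$gene_id, top$rank_sum))
  } else {
    lines <- c(lines, "", "Consensus set is empty.")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
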