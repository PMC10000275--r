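# Sample QC, TMM-scaled CPM normalization, expression-detection filters
# and age-group composition summaries.

#' Sample quality-control thresholds
#'
#' ERCC-style criteria for circulating small RNA libraries: at least
#' 100,000 reads aligned to annotated RNA transcripts (inclusive) and a
#' transcriptome/total read ratio strictly greater than 0.5.
#'
#' @param min_transcriptome_reads Minimum transcriptome-aligned reads
#'   (inclusive).
#' @param min_transcriptome_ratio Transcriptome/total ratio that must be
#'   strictly exceeded.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_transcriptome_reads = 1e5,
                          min_transcriptome_ratio = 0.5) {
  if (min_transcriptome_reads <= 0 || min_transcriptome_ratio <= 0) {
    abort("QC thresholds must be positive")
  }
  structure(list(min_transcriptome_reads = min_transcriptome_reads,
                 min_transcriptome_ratio = min_transcriptome_ratio),
            class = "qc_thresholds")
}

#' Age-group boundaries
#'
#' Defaults to the conventional young (20--30), adult (31--60) and aged
#' (61+) grouping, with ages taken as integer years and all intervals
#' closed.
#'
#' @param boundaries Named list of length-2 numeric intervals; must be
#'   disjoint and ordered.
#' @return An `age_grouping` object.
#' @export
age_grouping <- function(boundaries = list(young = c(20, 30),
                                           adult = c(31, 60),
                                           aged = c(61, Inf))) {
  lo <- vapply(boundaries, `[`, numeric(1), 1)
  hi <- vapply(boundaries, `[`, numeric(1), 2)
  if (any(lo > hi)) abort("each age interval must be increasing")
  if (is.unsorted(lo) || any(utils::head(hi, -1) >= lo[-1])) {
    abort("age intervals must be disjoint and ordered")
  }
  structure(list(boundaries = boundaries), class = "age_grouping")
}

#' Assign samples to age groups
#'
#' @param age Numeric vector of ages in years.
#' @param grouping An [age_grouping()].
#' @return Factor of group labels (levels in grouping order); ages falling
#'   outside every interval become `NA`.
#' @export
assign_age_group <- function(age, grouping = age_grouping()) {
  labels <- names(grouping$boundaries)
  out <- rep(NA_character_, length(age))
  for (lab in labels) {
    b <- grouping$boundaries[[lab]]
    out[age >= b[1] & age <= b[2]] <- lab
  }
  factor(out, levels = labels)
}

#' Expression-detection rule
#'
#' A gene counts as detected when at least `min_fraction` of the samples of
#' an age group show `>= min_cpm` CPM. With `scope = "any_group"` (the
#' default) one qualifying group suffices; `"all_groups"` requires every
#' nonempty group to qualify.
#'
#' @param min_cpm CPM threshold (inclusive).
#' @param min_fraction Fraction of a group's samples required (inclusive).
#' @param scope `"any_group"` or `"all_groups"`.
#' @return A `detection_rule` list.
#' @export
detection_rule <- function(min_cpm = 1, min_fraction = 0.30,
                           scope = c("any_group", "all_groups")) {
  scope <- match.arg(scope)
  if (min_cpm <= 0) abort("min_cpm must be > 0")
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must be in (0, 1]")
  }
  structure(list(min_cpm = min_cpm, min_fraction = min_fraction,
                 scope = scope), class = "detection_rule")
}

#' Filter samples on sequencing quality
#'
#' @param meta Sample metadata with `sample_id`, `transcriptome_reads` and
#'   `total_reads` columns.
#' @param thresholds A [qc_thresholds()].
#' @return List with `retained` (character vector of sample ids) and
#'   `audit` (tibble with per-sample pass/fail and the rule that failed).
#' @export
qc_filter <- function(meta, thresholds = qc_thresholds()) {
  need <- c("sample_id", "transcriptome_reads", "total_reads")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- meta$sample_id[!complete.cases(
    meta[c("transcriptome_reads", "total_reads")])]
  if (length(bad)) {
    abort(paste0("missing read counts for sample(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  audit <- meta |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::mutate(
      transcriptome_ratio = .data$transcriptome_reads / .data$total_reads,
      pass_reads = .data$transcriptome_reads >=
        thresholds$min_transcriptome_reads,
      pass_ratio = .data$transcriptome_ratio >
        thresholds$min_transcriptome_ratio,
      retained = .data$pass_reads & .data$pass_ratio,
      failed_rule = dplyr::case_when(
        !pass_reads & !pass_ratio ~ "reads+ratio",
        !pass_reads ~ "reads",
        !pass_ratio ~ "ratio",
        TRUE ~ NA_character_
      )
    )
  list(retained = audit$sample_id[audit$retained], audit = audit)
}

# edgeR-convention TMM for one sample against the reference
tmm_one <- function(obs, ref, nO, nR, logratio_trim = 0.30, sum_trim = 0.05) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]
  absE <- absE[fin]
  v <- v[fin]
  if (length(logR) == 0) {
    abort("a sample shares no positive genes with the reference")
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM recipe: against a
#' reference sample (the one whose 75th-percentile count fraction is
#' closest to the mean), gene-wise log-ratios (M) and average log
#' abundances (A) over doubly positive genes are trimmed (30% on M, 5% on
#' A) and the surviving M values averaged with inverse asymptotic-variance
#' weights. Factors are rescaled to geometric mean 1.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param lib_size Optional per-sample library sizes; defaults to column
#'   sums.
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_size = NULL) {
  m <- expr_to_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  lib_size <- lib_size %||% colSums(m)
  if (any(lib_size <= 0)) abort("every sample needs a positive library size")
  f75 <- apply(m, 2, function(x) quantile(x, 0.75)) / lib_size
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    tmm_one(m[, j], m[, ref], lib_size[j], lib_size[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Counts per million on (optionally TMM-) normalized library sizes
#'
#' `CPM_gs = count_gs / (lib_size_s * factor_s) * 1e6`.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param factors Per-sample normalization factors (e.g. from
#'   [tmm_factors()]); default 1 for every sample.
#' @param lib_size Optional library sizes; defaults to column sums.
#' @return Expression tibble of CPM values, same shape as `counts`.
#' @export
cpm_normalize <- function(counts, factors = NULL, lib_size = NULL) {
  m <- expr_to_matrix(counts)
  lib_size <- lib_size %||% colSums(m)
  if (any(lib_size <= 0)) abort("zero library size")
  factors <- factors %||% setNames(rep(1, ncol(m)), colnames(m))
  if (!is.null(names(factors))) factors <- factors[colnames(m)]
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("normalization factors must be positive, one per sample")
  }
  out <- sweep(m, 2, lib_size * factors, `/`) * 1e6
  matrix_to_expr(out)
}

#' Detection filter over age groups
#'
#' @param expr CPM expression tibble.
#' @param meta Sample metadata with `age`.
#' @param grouping An [age_grouping()].
#' @param rule A [detection_rule()].
#' @return Character vector of gene ids passing the rule.
#' @export
detection_filter <- function(expr, meta, grouping = age_grouping(),
                             rule = detection_rule()) {
  m <- expr_to_matrix(expr)
  meta <- align_meta(expr, meta)
  grp <- assign_age_group(meta$age, grouping)
  if (anyNA(grp)) abort("every sample must fall into exactly one age group")
  labels <- levels(grp)
  empty <- labels[!labels %in% grp]
  if (length(empty)) {
    warn(paste0("empty age group(s): ", paste(empty, collapse = ", "),
                "; they cannot qualify a gene"))
  }
  hit <- m >= rule$min_cpm
  frac_by_group <- vapply(labels, function(lab) {
    cols <- which(grp == lab)
    if (!length(cols)) return(rep(NA_real_, nrow(m)))
    rowMeans(hit[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  qual <- frac_by_group >= rule$min_fraction
  keep <- if (rule$scope == "any_group") {
    apply(qual, 1, function(r) any(r, na.rm = TRUE))
  } else {
    apply(qual, 1, function(r) all(r[!is.na(r)]) && any(!is.na(r)))
  }
  rownames(m)[keep]
}

#' Biotype composition by age group
#'
#' For each age group, counts highly expressed genes per biotype (after
#' [detection_filter()] within that group at `rule`) and sums their CPM;
#' shares sum to one per group.
#'
#' @param expr CPM expression tibble.
#' @param biotypes Tibble with `gene_id` and `biotype` columns.
#' @param meta Sample metadata with `age`.
#' @param grouping An [age_grouping()].
#' @param rule A [detection_rule()]; defaults to the highly expressed
#'   cutoff (10 CPM in 30% of a group's samples).
#' @return Tibble with one row per group x biotype: `n_genes`,
#'   `gene_share`, `total_cpm`, `cpm_share`.
#' @export
composition_summary <- function(expr, biotypes, meta,
                                grouping = age_grouping(),
                                rule = detection_rule(min_cpm = 10)) {
  if (!all(expr$gene_id %in% biotypes$gene_id)) {
    abort("every gene needs a biotype")
  }
  m <- expr_to_matrix(expr)
  meta <- align_meta(expr, meta)
  grp <- assign_age_group(meta$age, grouping)
  bio <- biotypes$biotype[match(rownames(m), biotypes$gene_id)]
  purrr::map_dfr(levels(grp), function(lab) {
    cols <- which(grp == lab)
    if (!length(cols)) return(NULL)
    sub <- m[, cols, drop = FALSE]
    frac <- rowMeans(sub >= rule$min_cpm)
    keep <- frac >= rule$min_fraction
    if (!any(keep)) {
      return(tibble::tibble(age_group = lab, biotype = character(),
                            n_genes = integer(), gene_share = numeric(),
                            total_cpm = numeric(), cpm_share = numeric()))
    }
    tibble::tibble(biotype = bio[keep],
                   total = rowSums(sub[keep, , drop = FALSE])) |>
      dplyr::group_by(.data$biotype) |>
      dplyr::summarise(n_genes = dplyr::n(),
                       total_cpm = sum(.data$total), .groups = "drop") |>
      dplyr::mutate(age_group = lab,
                    gene_share = .data$n_genes / sum(.data$n_genes),
                    cpm_share = .data$total_cpm / sum(.data$total_cpm)) |>
      dplyr::select("age_group", "biotype", "n_genes", "gene_share",
                    "total_cpm", "cpm_share")
  })
}
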