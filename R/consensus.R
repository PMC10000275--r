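# Rank-sum consensus across the three tree-ensemble importance vectors:
# genes are ranked per method (1 = largest impurity importance, zeros
# unranked), the ranks summed, and genes ranked by every method form the
# core age-related set.

#' Collect importance tables from fitted models
#'
#' @param fits Named list of `snc_cv` (or `snc_model`) objects; names
#'   default to each spec's method.
#' @return Long tibble with `method`, `gene_id`, `importance`.
#' @export
collect_importances <- function(fits) {
  nm <- names(fits) %||% purrr::map_chr(fits, ~ .x$spec$method)
  if (is.null(names(fits))) names(fits) <- nm
  purrr::imap_dfr(fits, function(f, method) {
    imp <- if (inherits(f, "snc_cv")) f$importance else {
      if (is.null(f$importance)) NULL else
        tibble::tibble(gene_id = names(f$importance),
                       importance = as.numeric(f$importance))
    }
    if (is.null(imp)) return(NULL)
    dplyr::bind_cols(tibble::tibble(method = method), imp)
  })
}

#' Per-method importance ranks
#'
#' Rank 1 is the largest importance within a method; genes with zero
#' importance receive no rank; ties break lexicographically by gene id so
#' ranking is deterministic.
#'
#' @param importances Long tibble with `method`, `gene_id`, `importance`
#'   (e.g. from [collect_importances()]).
#' @param rank_zeros Also rank zero-importance genes (off by default).
#' @return Tibble with `method`, `gene_id`, `importance`, `rank`.
#' @export
importance_ranks <- function(importances, rank_zeros = FALSE) {
  if (nrow(importances) == 0) abort("empty importance table")
  if (any(importances$importance < 0)) abort("importances must be >= 0")
  importances |>
    dplyr::group_by(.data$method) |>
    dplyr::filter(rank_zeros | .data$importance > 0) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Rank-sum consensus table of core age-related genes
#'
#' @param ranks Tibble from [importance_ranks()] covering the three
#'   ensemble methods (or any set of methods).
#' @param top_n Optionally truncate the core set to the `top_n` smallest
#'   rank sums.
#' @param methods Methods that must all rank a gene; defaults to every
#'   method present in `ranks`.
#' @return Tibble sorted by ascending `rank_sum` (ties by gene id): one
#'   `rank_<method>` column per method, `in_all` (ranked by every
#'   method), `rank_sum` (`NA` unless ranked everywhere) and `core`.
#' @export
rank_sum_core <- function(ranks, top_n = NULL, methods = NULL) {
  methods <- methods %||% unique(ranks$method)
  wide <- ranks |>
    dplyr::filter(.data$method %in% methods) |>
    dplyr::select("gene_id", "method", "rank") |>
    tidyr::pivot_wider(names_from = "method", values_from = "rank",
                       names_prefix = "rank_")
  rank_cols <- paste0("rank_", methods)
  rank_mat <- as.matrix(wide[rank_cols])
  in_all <- rowSums(is.na(rank_mat)) == 0
  rank_sum <- ifelse(in_all, rowSums(rank_mat), NA_integer_)
  out <- wide |>
    dplyr::mutate(in_all = in_all, rank_sum = as.integer(rank_sum)) |>
    dplyr::arrange(dplyr::desc(.data$in_all), .data$rank_sum,
                   .data$gene_id)
  core <- out$in_all
  if (!is.null(top_n)) {
    core <- core & seq_len(nrow(out)) <= top_n
  }
  out$core <- core
  out
}

#' Write a consensus table in the conventional column layout
#'
#' Columns: `input_label`, `gene`, `rna_type`, one per-method rank column,
#' `sum_of_rank`.
#'
#' @param consensus Tibble from [rank_sum_core()].
#' @param path Output path.
#' @param input_label Label for the screened input set.
#' @param biotypes Optional tibble with `gene_id`, `biotype`.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(consensus, path, input_label = "MIC",
                                biotypes = NULL) {
  out <- consensus |>
    dplyr::mutate(input_label = input_label,
                  rna_type = if (is.null(biotypes)) NA_character_ else
                    biotypes$biotype[match(.data$gene_id,
                                           biotypes$gene_id)]) |>
    dplyr::rename(gene = "gene_id", sum_of_rank = "rank_sum") |>
    dplyr::select("input_label", "gene", "rna_type",
                  dplyr::starts_with("rank_"), "sum_of_rank", "core")
  readr::write_tsv(out, path)
  invisible(path)
}
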