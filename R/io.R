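# Tab-delimited readers/writers for the pipeline's tabular artifacts.
# Counts and expression matrices are genes x samples with a `gene_id`
# first column; metadata and result tables are one row per record with a
# header row. An optional MatrixMarket-style triplet format is supported
# for large count matrices.

#' Write a gene-by-sample matrix as tab-delimited text
#'
#' @param expr Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(expr, path) {
  stopifnot("gene_id" %in% names(expr))
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read a gene-by-sample matrix written by [write_expr_tsv()]
#'
#' @param path File path; first column must be `gene_id`.
#' @return Tibble with `gene_id` plus one numeric column per sample.
#' @export
read_expr_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(out)[1] != "gene_id") {
    abort("expected a `gene_id` first column")
  }
  out
}

#' Write or read a table of per-record results
#'
#' Thin wrappers over tab-delimited text used for sample metadata, audit
#' tables, association tables and consensus tables.
#'
#' @param tbl A data frame.
#' @param path File path.
#' @return `write_table_tsv()` returns `path` invisibly;
#'   `read_table_tsv()` returns a tibble.
#' @export
write_table_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write counts in MatrixMarket-style sparse triplet form
#'
#' Rows are genes, columns samples; only nonzero entries are stored. Gene
#' and sample identifiers are written to `<path>.rownames` /
#' `<path>.colnames` companions.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  m <- expr_to_matrix(counts)
  idx <- which(m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx)), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d %d %d", idx[, 1], idx[, 2], m[idx]), con)
  }
  writeLines(rownames(m), paste0(path, ".rownames"))
  writeLines(colnames(m), paste0(path, ".colnames"))
  invisible(path)
}

#' Read counts written by [write_counts_mtx()]
#'
#' @param path `.mtx` path with `.rownames`/`.colnames` companions.
#' @return Count tibble (`gene_id` + sample columns).
#' @export
read_counts_mtx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  dims <- scan(text = lines[1], what = integer(), quiet = TRUE)
  m <- matrix(0, nrow = dims[1], ncol = dims[2])
  if (dims[3] > 0) {
    trip <- matrix(scan(text = lines[-1], what = double(), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
    m[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  }
  rownames(m) <- readLines(paste0(path, ".rownames"))
  colnames(m) <- readLines(paste0(path, ".colnames"))
  matrix_to_expr(m)
}
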