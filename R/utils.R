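# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Counts/expression travel as tibbles with a `gene_id` first column and one
# column per sample; these two convert to/from the plain numeric matrix the
# numerical code wants.
expr_to_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "gene_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  rownames(m) <- tbl$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, rownames = "gene_id")
}

# Align metadata rows to the sample columns of an expression tibble.
align_meta <- function(expr, meta) {
  samples <- setdiff(names(expr), "gene_id")
  if (!all(samples %in% meta$sample_id)) {
    missing <- setdiff(samples, meta$sample_id)
    abort(paste0("metadata is missing sample(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  meta[match(samples, meta$sample_id), , drop = FALSE]
}

check_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single number in [0, 1]"))
  }
  invisible(x)
}
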