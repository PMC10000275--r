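# Maximal / total information coefficient computation and the
# dual-threshold age-association screen. The characteristic matrix is
# built from scratch (src/mine.cpp): for every grid shape (k x l) within
# the budget B(n) = ceiling(n^alpha), one axis is equipartitioned and the
# other optimized by the clump-merging dynamic program, in both
# orientations; entries are maximal mutual information normalized by
# log2(min(k, l)).

#' Parameters of the MIC estimator
#'
#' @param alpha Grid-budget exponent: grids with `k*l <= ceiling(n^alpha)`
#'   are searched. Must lie in (0, 1).
#' @param c Clump factor: the optimized axis may use up to `c * k`
#'   candidate clumps before merging.
#' @param both_orientations Compute each grid shape with the axes swapped
#'   as well and take the elementwise maximum (makes MIC symmetric).
#' @return A `mine_params` list.
#' @export
mine_params <- function(alpha = 0.6, c = 15, both_orientations = TRUE) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (c < 1) abort("c must be >= 1")
  structure(list(alpha = alpha, c = as.integer(c),
                 both_orientations = isTRUE(both_orientations)),
            class = "mine_params")
}

check_mine_input <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 10) abort("need at least 10 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (min(x) == max(x) || min(y) == max(y)) {
    abort("association with a constant vector is undefined")
  }
  invisible(TRUE)
}

#' Characteristic matrix of normalized maximal mutual information
#'
#' @param x,y Numeric vectors of equal length (n >= 10), not constant.
#' @param params A [mine_params()].
#' @return Numeric matrix whose `[k-1, l-1]` entry (dimnames give k, l) is
#'   the normalized maximal mutual information of the best k x l grid;
#'   shapes outside the budget are `NA`.
#' @export
characteristic_matrix <- function(x, y, params = mine_params()) {
  check_mine_input(x, y)
  cm <- cpp_char_matrix(as.numeric(x), as.numeric(y), params$alpha,
                        params$c, params$both_orientations)
  shapes <- as.character(seq(2, nrow(cm) + 1))
  dimnames(cm) <- list(k = shapes, l = shapes)
  cm
}

#' Maximal and total information coefficients
#'
#' MIC is the maximum entry of the characteristic matrix; TIC is reported
#' both as the mean over computed entries (a \[0, 1\] statistic, the
#' package default for thresholding) and as the unnormalized sum.
#'
#' @inheritParams characteristic_matrix
#' @return List with `mic`, `tic` (mean-normalized) and `tic_sum`.
#' @export
mic_tic <- function(x, y, params = mine_params()) {
  cm <- characteristic_matrix(x, y, params)
  v <- cm[!is.na(cm)]
  list(mic = max(v), tic = mean(v), tic_sum = sum(v))
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return The coefficient of determination of the linear fit of `y` on
#'   `x` (equivalently the squared correlation).
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("pearson_r2 is undefined for constant input")
  }
  cor(x, y)^2
}

#' MIC/TIC age-association screen
#'
#' Computes per-gene MIC, TIC, squared Pearson correlation with age and
#' the nonlinearity diagnostic `mic - pearson_r2`; genes pass when both
#' MIC and TIC reach `threshold` (inclusive by default).
#'
#' @param expr Expression tibble (`gene_id` + sample columns), typically
#'   batch-corrected CPM of expressed genes.
#' @param ages Numeric ages aligned with the sample columns.
#' @param threshold Dual threshold applied to MIC and TIC.
#' @param params A [mine_params()].
#' @param strict If `TRUE`, require MIC and TIC strictly greater than the
#'   threshold instead of `>=`.
#' @return Tibble (one row per gene, sorted by MIC descending):
#'   `gene_id`, `mic`, `tic`, `pearson_r2`, `nonlinearity`, `passes`.
#' @export
mic_screen <- function(expr, ages, threshold = 0.7,
                       params = mine_params(), strict = FALSE) {
  m <- expr_to_matrix(expr)
  if (ncol(m) != length(ages)) {
    abort("`ages` must align with the sample columns of `expr`")
  }
  recs <- purrr::map(seq_len(nrow(m)), function(g) {
    xg <- m[g, ]
    if (min(xg) == max(xg)) {
      return(tibble::tibble(mic = NA_real_, tic = NA_real_,
                            pearson_r2 = NA_real_))
    }
    mt <- mic_tic(xg, ages, params)
    tibble::tibble(mic = mt$mic, tic = mt$tic,
                   pearson_r2 = pearson_r2(xg, ages))
  })
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          dplyr::bind_rows(recs)) |>
    dplyr::mutate(
      nonlinearity = .data$mic - .data$pearson_r2,
      passes = if (strict) {
        !is.na(.data$mic) & .data$mic > threshold & .data$tic > threshold
      } else {
        !is.na(.data$mic) & .data$mic >= threshold & .data$tic >= threshold
      }
    ) |>
    dplyr::arrange(dplyr::desc(.data$mic))
  out
}

#' Gene ids selected by a screen
#'
#' @param assoc The association tibble returned by [mic_screen()].
#' @return Character vector of passing gene ids.
#' @export
screen_selected <- function(assoc) {
  assoc$gene_id[assoc$passes]
}
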