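# ggplot2 figures for each result type.

#' Plot sample scores of the batch PCA diagnostic
#'
#' @param object An `snc_pca` from [pca_diagnostic()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2, colored by batch, shaped by age group.
#' @export
autoplot.snc_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2,
                                       color = .data$batch,
                                       shape = .data$age_group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
      subtitle = sprintf("PC1 ~ batch R² = %.2f", batch_r2(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot out-of-fold predicted vs actual age
#'
#' @param object An `snc_cv` from [fit_predict_cv()].
#' @param ... Unused.
#' @return A ggplot with the identity line and mean metrics in the
#'   subtitle.
#' @export
autoplot.snc_cv <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$age, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "chronological age (years)", y = "predicted age (years)",
      title = object$spec$method,
      subtitle = sprintf("out-of-fold R² = %.3f, RMSE = %.2f y, MAE = %.2f y",
                         s$r2, s$rmse, s$mae)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the MIC-vs-linearity diagnostic of an association screen
#'
#' MIC against squared Pearson correlation; points above the dashed
#' `mic - r2 = 0.2` guide behave nonlinearly.
#'
#' @param assoc Association tibble from [mic_screen()].
#' @param threshold Screen threshold drawn as a guide.
#' @return A ggplot.
#' @export
plot_association <- function(assoc, threshold = 0.7) {
  ggplot2::ggplot(assoc, ggplot2::aes(.data$pearson_r2, .data$mic,
                                      color = .data$passes)) +
    ggplot2::geom_abline(slope = 1, intercept = 0.2, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = expression(rho^2), y = "MIC") +
    ggplot2::theme_minimal()
}

#' Plot biotype composition by age group
#'
#' @param comp Tibble from [composition_summary()].
#' @param share `"gene_share"` or `"cpm_share"`.
#' @return A stacked-bar ggplot, one bar per age group.
#' @export
plot_composition <- function(comp, share = c("gene_share", "cpm_share")) {
  share <- match.arg(share)
  ggplot2::ggplot(comp, ggplot2::aes(.data$age_group,
                                     .data[[share]],
                                     fill = .data$biotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = gsub("_", " ", share)) +
    ggplot2::theme_minimal()
}
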