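#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA sample coordinates
#'
#' @param object A `geno_pca` from [pca_genotypes()].
#' @param ... Unused.
#' @return A ggplot: PC1 vs PC2 coloured by population.
#' @method autoplot geno_pca
#' @export
autoplot.geno_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = "population") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an iHS scan
#'
#' @param object An `ihs_scan` from [ihs()].
#' @param quantile Highlight threshold (top fraction of |iHS|).
#' @param ... Unused.
#' @return A ggplot of |standardized iHS| along the genome.
#' @method autoplot ihs_scan
#' @export
autoplot.ihs_scan <- function(object, quantile = 0.001, ...) {
  s <- object$sites[object$sites$valid, ]
  thr <- stats::quantile(abs(s$std_ihs), 1 - quantile, names = FALSE)
  ggplot2::ggplot(s, ggplot2::aes(.data$pos / 1e6, abs(.data$std_ihs))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_grid(. ~ scaffold, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "|standardized iHS|",
                  title = sprintf("iHS scan: %s", object$population)) +
    ggplot2::theme_minimal()
}

#' Plot the minor-allele-frequency spectrum
#'
#' @param spectrum A tibble from [maf_spectrum()].
#' @return A ggplot bar chart of per-bin SNP proportions.
#' @export
plot_maf_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(.data$bin, .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "minor allele frequency", y = "proportion of SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-population F_ROH
#'
#' @param froh_summary The result of [froh()] (with population summary).
#' @return A ggplot of mean F_ROH by population and size class.
#' @export
plot_froh <- function(froh_summary) {
  pp <- froh_summary$per_population
  ggplot2::ggplot(pp, ggplot2::aes(.data$population, .data$mean_froh,
                                   fill = .data$size_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_froh - .data$sd_froh,
                   ymax = .data$mean_froh + .data$sd_froh),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::labs(y = "F_ROH (genome fraction)", fill = "ROH class") +
    ggplot2::theme_minimal()
}
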