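#' Boxplot of cell reliability by method
#'
#' The reliability metric (variance of true discrepancies over variance of
#' estimates) per cell, by method. The EBD panel typically shows the heavy
#' right tail produced by over-shrinkage; `trim` caps the axis so the RSD and
#' SEM boxes stay readable.
#'
#' @param study A `dyad_study`.
#' @param trim Upper axis limit (`NULL` for no trimming).
#' @return A ggplot object.
#' @export
plot_reliability <- function(study, trim = 5) {
  cm <- study$cell_metrics
  p <- ggplot2::ggplot(cm, ggplot2::aes(x = toupper(.data$method),
                                        y = .data$reliability)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Var(true) / Var(estimate)",
                  title = "Reliability of discrepancy estimates by method")
  if (!is.null(trim)) p <- p + ggplot2::coord_cartesian(ylim = c(0, trim))
  p
}

#' Boxplot of a slope-bias metric by method
#'
#' @param study A `dyad_study`.
#' @param metric Cell-metric column (default the discrepancy-slope bias).
#' @return A ggplot object.
#' @export
plot_slope_bias <- function(study, metric = "slope_bias_discrepancy") {
  cm <- study$cell_metrics
  stopifnot(metric %in% names(cm))
  ggplot2::ggplot(cm, ggplot2::aes(x = toupper(.data$method),
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = metric)
}

#' Outlier fractions by ICC and number of dyads
#'
#' Visualises where EBD over-shrinkage concentrates: the fraction of flagged
#' EBD cells (or replications) in each ICC x cluster-number stratum.
#'
#' @param outliers An `ebd_outliers` object from [flag_ebd_outliers()].
#' @return A ggplot object.
#' @export
plot_outliers <- function(outliers) {
  ct <- outliers$crosstab
  if (is.null(ct)) abort("no ICC x n_dyads cross-tab available",
                         class = "dyadsim_config_error")
  ggplot2::ggplot(ct, ggplot2::aes(x = factor(.data$n_dyads),
                                   y = .data$fraction,
                                   fill = factor(.data$icc))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of dyads", y = "fraction flagged",
                  fill = "ICC",
                  title = "EBD outliers by ICC and cluster number")
}

#' @method autoplot dyad_study
#' @export
autoplot.dyad_study <- function(object, ...) {
  plot_reliability(object, ...)
}

#' @method autoplot ebd_outliers
#' @export
autoplot.ebd_outliers <- function(object, ...) {
  plot_outliers(object)
}
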