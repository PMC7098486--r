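#' Plot a profile spectrum
#'
#' @param spectrum Tibble with `mz` and `intensity`.
#' @param xlim Optional m/z range to zoom into.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, xlim = NULL) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(.data$mz, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "Intensity") +
    ggplot2::theme_minimal()
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}

#' Bar plot of recovered Ub^dGG proteoform fractions
#'
#' @param quant Result of [quantify_ub_proteoforms()] (or any tibble with
#'   `proteoform` and `percent`).
#' @param log_scale Show percentages on a log10 axis (the minor species
#'   span three orders of magnitude)?
#' @return A ggplot.
#' @export
plot_proteoform_fractions <- function(quant, log_scale = TRUE) {
  p <- ggplot2::ggplot(quant,
                       ggplot2::aes(.data$proteoform, .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Volcano plot of a differential-abundance fit
#'
#' Dotted outlines mark features past the fold-change/p thresholds;
#' filled points are significant by permutation FDR.
#'
#' @param object An `ub_diff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ub_diff <- function(object, ...) {
  res <- object$result
  res$neglog10p <- -log10(res$p)
  ggplot2::ggplot(res, ggplot2::aes(.data$log2_ratio, .data$neglog10p)) +
    ggplot2::geom_point(data = res[res$category == "ns", ],
                        color = "grey70", size = 0.8) +
    ggplot2::geom_point(data = res[res$category != "ns" & !res$significant, ],
                        ggplot2::aes(color = .data$category),
                        shape = 1, size = 1.2) +
    ggplot2::geom_point(data = res[res$significant, ],
                        ggplot2::aes(color = .data$category), size = 1.4) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                           ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$log2_threshold,
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(object$params$p_threshold),
                        linetype = "dotted") +
    ggplot2::labs(x = "log2 ratio", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mitophagic-flux time course
#'
#' @param ratios Tibble from [keima_ratio()] with `timepoint_h`,
#'   `genotype` and `keima_ratio`.
#' @return A ggplot of mean +/- SEM per condition.
#' @export
plot_flux_trajectory <- function(ratios) {
  summ <- ratios |>
    dplyr::group_by(.data$genotype, .data$timepoint_h) |>
    dplyr::summarise(mean = mean(.data$keima_ratio),
                     sem = stats::sd(.data$keima_ratio) /
                       sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$timepoint_h, .data$mean,
                                     color = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "Depolarization (h)",
                  y = "Processed / unprocessed reporter") +
    ggplot2::theme_minimal()
}
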