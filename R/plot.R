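#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a selection-scan result
#'
#' Scatter of the two gene-level scan metrics — mean fixation index against
#' the \eqn{-\log_{10}} HA/LA diversity ratio — with the nearest-rank decile
#' cutoffs as dashed lines and candidate genes highlighted. Genes with an
#' infinite ratio (zero HA diversity) are drawn as triangles pinned just
#' above the largest finite ratio.
#'
#' @param object An `altiscan_scan` object from [run_selection_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot altiscan_scan
#' @export
autoplot.altiscan_scan <- function(object, ...) {
  genes <- object$genes
  genes <- genes[!is.na(genes$mean_fst) & !is.na(genes$ratio), , drop = FALSE]
  finite <- genes$ratio[is.finite(genes$ratio)]
  cap <- if (length(finite) > 0) max(finite) * 1.05 + 0.1 else 1
  genes$ratio_plot <- ifelse(is.finite(genes$ratio), genes$ratio, cap)
  genes$shape <- ifelse(is.finite(genes$ratio), "finite", "infinite")
  thr_ratio <- object$thresholds[["ratio"]]
  ggplot2::ggplot(
    genes,
    ggplot2::aes(
      x = .data$mean_fst, y = .data$ratio_plot,
      colour = .data$candidate, shape = .data$shape
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(
      xintercept = object$thresholds[["fst"]], linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = if (is.finite(thr_ratio)) thr_ratio else cap,
      linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#d95f02", `FALSE` = "grey50"),
      name = "candidate"
    ) +
    ggplot2::scale_shape_manual(
      values = c(finite = 16, infinite = 17), guide = "none"
    ) +
    ggplot2::labs(
      x = "mean per-gene Fst",
      y = expression(-log[10] * "(" * pi[HA] / pi[LA] * ")"),
      title = "Gene-level selection scan"
    ) +
    ggplot2::theme_minimal()
}

#' Plot windowed Tajima's D along contigs
#'
#' @param windows Output of [windowed_tajimas_d()] for one or both
#'   populations (rows may be bound together).
#' @return A ggplot object: D against window midpoint, faceted by contig,
#'   coloured by population; windows with undefined D are omitted.
#' @export
plot_windowed_d <- function(windows) {
  w <- windows[!is.na(windows$tajimas_d), , drop = FALSE]
  ggplot2::ggplot(
    w,
    ggplot2::aes(
      x = (.data$start + .data$end) / 2, y = .data$tajimas_d,
      colour = .data$population
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)", y = "Tajima's D") +
    ggplot2::theme_minimal()
}
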