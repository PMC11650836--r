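# Thin ggplot2 layer over the plot-ready series. The tested contract is the
# series content; these helpers only render it.

#' Render an MLPA-like per-exon boxplot
#'
#' @param series Series from [boxplot_series()].
#' @param metric `"log2"` or `"depth"`.
#' @return A ggplot object.
#' @export
plot_boxplot_series <- function(series, metric = c("log2", "depth")) {
  metric <- match.arg(metric)
  col <- function(stat) series[[paste0(metric, "_", stat)]]
  df <- tibble::tibble(
    exon_index = series$exon_index,
    q1 = col("q1"), median = col("median"), q3 = col("q3"),
    lo = col("whisker_low"), hi = col("whisker_high"),
    sample = series[[paste0("sample_", metric)]]
  )
  th <- attr(series, "thresholds")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$exon_index)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3), fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(y = .data$sample), colour = "red", size = 2,
                        na.rm = TRUE) +
    ggplot2::labs(title = attr(series, "gene"), x = "exon",
                  y = if (metric == "log2") "log2 coverage ratio" else "raw depth")
  if (metric == "log2" && !is.null(th)) {
    p <- p +
      ggplot2::geom_hline(yintercept = th$dup_log2, linetype = "dashed", colour = "blue") +
      ggplot2::geom_hline(yintercept = th$het_del_log2, linetype = "dashed", colour = "salmon") +
      ggplot2::geom_hline(yintercept = th$hom_del_log2, linetype = "dashed", colour = "red")
  }
  p
}

#' Render the log2 scatter series
#'
#' @param series List from [scatter_series()].
#' @return A ggplot object.
#' @export
plot_scatter_series <- function(series) {
  ggplot2::ggplot(series$points,
                  ggplot2::aes(x = .data$position_genome, y = .data$log2,
                               colour = .data$in_called_segment)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "genome position", y = "log2 coverage ratio",
                  colour = "called segment")
}

#' Render the B-allele-frequency series
#'
#' @param series Tibble from [baf_series()].
#' @param loh Optional LOH intervals from [detect_loh()], shaded.
#' @return A ggplot object.
#' @export
plot_baf_series <- function(series, loh = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$position, y = .data$frequency)) +
    ggplot2::geom_point(size = 0.6, colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position", y = "B-allele frequency")
  if (!is.null(loh) && nrow(loh) > 0) {
    p <- p + ggplot2::geom_rect(
      data = loh,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange"
    )
  }
  p
}
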