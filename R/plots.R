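#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_boxplot facet_wrap
#'   labs theme_minimal autoplot scale_y_log10 geom_vline
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a GC content / skew profile
#'
#' Three stacked panels: windowed GC content, GC skew and cumulative skew;
#' the cumulative-skew extrema mark the replication origin and terminus.
#'
#' @param object a `skew_profile` from [gc_profile()].
#' @param origin optional origin call from [predict_origin()], drawn as a
#'   vertical line.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot skew_profile
autoplot.skew_profile <- function(object, origin = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("gc_content", "gc_skew", "cumulative_skew"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("gc_content", "gc_skew", "cumulative_skew"))
  p <- ggplot(long, aes(x = .data$center, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~metric, ncol = 1, scales = "free_y") +
    labs(x = "genome position (bp)", y = NULL) +
    theme_minimal()
  if (!is.null(origin)) {
    p <- p + geom_vline(xintercept = origin$origin_pos, linetype = 2,
                        colour = "firebrick")
  }
  p
}

#' Plot per-lineage event counts
#'
#' @param summary result of [summarize_events()] (or a `reduction_analysis`).
#' @return a ggplot of missing/eroded and frameshifted gene counts per
#'   lineage.
#' @export
plot_lineage_events <- function(summary) {
  if (inherits(summary, "reduction_analysis")) summary <- summary$summary
  long <- tidyr::pivot_longer(summary$lineage_counts,
                              c("missing_or_eroded", "frameshifted"),
                              names_to = "class", values_to = "n")
  ggplot(long, aes(x = .data$lineage, y = .data$n, fill = .data$class)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "genes", fill = NULL) +
    theme_minimal()
}

#' Plot IGS length classes
#'
#' Log-scale boxplots of intergenic spacer lengths, split into spacers
#' spanning missing genes versus spacers between conserved genes.
#'
#' @param igs the `igs` tibble from [igs_classify_and_compare()] (or a
#'   `reduction_analysis`).
#' @return a ggplot.
#' @export
plot_igs_classes <- function(igs) {
  if (inherits(igs, "reduction_analysis")) igs <- igs$igs$igs
  if (is.list(igs) && !is.data.frame(igs)) igs <- igs$igs
  d <- mutate(igs, class = ifelse(.data$spans_missing, "spanning", "conserved"),
              length1 = .data$length + 1)
  ggplot(d, aes(x = .data$genome, y = .data$length1, fill = .data$class)) +
    geom_boxplot(outlier.size = 0.5) +
    scale_y_log10() +
    labs(x = NULL, y = "IGS length + 1 (bp)", fill = NULL) +
    theme_minimal()
}
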