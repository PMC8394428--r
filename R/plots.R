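# ggplot2 visualisations for traces, expression summaries and odds ratios.

#' Plot a calcium trace
#'
#' Bin-median fluorescence against time, with the stimulus-addition time
#' marked when the trace records one.
#'
#' @param object A `ccr5_trace` from [build_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccr5_trace
#' @export
autoplot.ccr5_trace <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t_mid, y = .data$mfi)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "fluo-4 MFI (a.u.)",
                  title = attr(object, "stimulus") %||% NULL)
  stim <- attr(object, "stim_time_s", exact = TRUE)
  if (!is.null(stim)) {
    p <- p + ggplot2::geom_vline(xintercept = stim, linetype = "dashed")
  }
  p
}

#' Plot per-genotype expression summaries
#'
#' Boxplots with jittered subject points of percent CCR5-positive monocytes
#' (or MFI) by genotype.
#'
#' @param summaries Tibble from [expression_cohort_summaries()] (or any
#'   table with `genotype` and the chosen column).
#' @param what `"pct_positive"` or `"mfi"`.
#' @return A ggplot object.
#' @export
plot_expression_by_genotype <- function(summaries,
                                        what = c("pct_positive", "mfi")) {
  what <- match.arg(what)
  lab <- c(pct_positive = "CCR5+ monocytes (%)",
           mfi = "CCR5 MFI (a.u.)")[[what]]
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$genotype, y = .data[[what]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = "rs1799987 genotype", y = lab)
}

#' Forest-style plot of odds ratios
#'
#' @param object A `ccr5_or`, or a tibble of tidied odds ratios with a
#'   `model` column (e.g. `tidy(association_report(...))`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ccr5_or
#' @export
autoplot.ccr5_or <- function(object, ...) {
  d <- tidy(object)
  d$model <- "odds ratio"
  plot_or_forest(d)
}

#' @rdname autoplot.ccr5_or
#' @param d Tibble with `model`, `estimate`, `conf.low`, `conf.high`.
#' @export
plot_or_forest <- function(d) {
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL)
}
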