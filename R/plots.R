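# Plot helpers.  The numeric content of each figure is always available as
# a plain data frame (log_ratio_summary(), as.data.frame.subsample_curve());
# these functions only render it when ggplot2 is available.

#' Per-sample log-ratio plot split by true label
#'
#' Jittered per-sample `log(score / threshold)` by group; everything above
#' the zero line is called anomalous.
#'
#' @param table a labeled `score_table`.
#' @return a ggplot object.
#' @export
plot_log_ratio <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_txa("plot_log_ratio needs the ggplot2 package")
  }
  check_score_table(table)
  df <- table[!is.na(table$true_label), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_label, y = .data$log_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "log(score / threshold)") +
    ggplot2::theme_bw()
}

#' Specificity versus training-set size
#'
#' Mean specificity across bootstraps with the per-bootstrap points.
#'
#' @param curve a `subsample_curve`.
#' @return a ggplot object.
#' @export
plot_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_txa("plot_curve needs the ggplot2 package")
  }
  stopifnot(inherits(curve, "subsample_curve"))
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$specificity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_specificity),
                       linewidth = 0.8, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training samples", y = "specificity") +
    ggplot2::theme_bw()
}
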