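# ggplot2 displays for result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Monte-Carlo simulation report
#'
#' One panel per performance measure (bias, MSE, coverage), estimators on
#' the x axis, across-run intervals as error bars; the nominal coverage and
#' zero-bias reference lines are drawn dashed.
#'
#' @param object A `sim_report` from [run_sim_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, mu = .data$mu_x - .data$mu_y),
    cols = c("bias_x1000", "mse_x10000", "coverage_pct"),
    names_to = "measure", values_to = "value"
  )
  long$lo <- dplyr::case_when(
    long$measure == "bias_x1000" ~ long$bias_lo,
    long$measure == "mse_x10000" ~ long$mse_lo,
    TRUE ~ long$coverage_lo
  )
  long$hi <- dplyr::case_when(
    long$measure == "bias_x1000" ~ long$bias_hi,
    long$measure == "mse_x10000" ~ long$mse_hi,
    TRUE ~ long$coverage_hi
  )
  ref <- tibble::tibble(
    measure = c("bias_x1000", "coverage_pct"),
    yintercept = c(0, 100 * attr(object, "config")$conf_level)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     colour = factor(.data$mu))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "shift") +
    ggplot2::theme_bw()
}

#' Plot a corrected-AUC report
#'
#' Forest-style display of the observed and corrected AUC estimates with
#' their confidence intervals.
#'
#' @param object An `auc_correction_tbl` from [correct_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.auc_correction_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "AUC", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_bw()
}

#' Histograms of a biomarker dataset
#'
#' Per-group, per-replicate histograms; useful for spotting skewness that
#' violates normal-theory corrections.
#'
#' @param data A biomarker data frame.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_biomarker_hist <- function(data, bins = 30) {
  .check_biomarker(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_grid(replicate ~ group, scales = "free") +
    ggplot2::labs(x = "biomarker value", y = "count") +
    ggplot2::theme_bw()
}
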