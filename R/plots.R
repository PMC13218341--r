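#' @title Plots
#' @name plots
#' @description ggplot2 graphics for the study outputs: per-condition
#'   outcomes with within-participant trajectories, the 2D-vs-3D agreement
#'   scatter, beam stress series and mesh-convergence curves.
NULL

#' Per-condition outcome plot with within-participant trajectories
#'
#' Individual participants as light lines across conditions, group
#' mean +/- SD overlaid - the standard repeated-measures display.
#'
#' @param outcomes tibble with `participant`, `condition` and the outcome.
#' @param outcome outcome column name (string).
#' @param condition_order condition display order.
#' @return a ggplot.
#' @export
plot_condition_outcomes <- function(outcomes, outcome = "peak_ant_MPa",
                                    condition_order = c("hRFS", "iRFS", "iFFS")) {
  df <- outcomes
  df$condition <- factor(df$condition, levels = condition_order)
  df$.y <- df[[outcome]]
  summ <- dplyr::summarise(dplyr::group_by(df, condition),
                           m = mean(.data$.y), s = stats::sd(.data$.y),
                           .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = .data$.y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       color = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(color = "grey60", size = 1) +
    ggplot2::geom_pointrange(data = summ,
                             ggplot2::aes(y = .data$m, ymin = .data$m - .data$s,
                                          ymax = .data$m + .data$s),
                             color = "black", linewidth = 0.6) +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}

#' 2D-vs-3D method agreement scatter (identity line)
#'
#' @param x a `method_agreement`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.method_agreement <- function(x, ...) {
  tab <- x$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pct_a, y = .data$pct_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "2D beam theory % change", y = "3D FEA % change") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Beam stress series over stance
#'
#' @param x a `beam_stress_series`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.beam_stress_series <- function(x, ...) {
  long <- tidyr::pivot_longer(x, c("sigma_ant_MPa", "sigma_post_MPa"),
                              names_to = "aspect", values_to = "MPa")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pct_stance, y = .data$MPa,
                                     color = .data$aspect)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(sigma_ant_MPa = "#D55E00",
                                           sigma_post_MPa = "#0072B2"),
                                labels = c("anterior", "posterior")) +
    ggplot2::labs(x = "% stance", y = "normal stress (MPa)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Mesh-convergence curves
#'
#' @param conv a [run_mesh_convergence()] result.
#' @return a ggplot of the three key metrics against element size
#'   (normalized to their finest-mesh value).
#' @export
plot_convergence <- function(conv) {
  tb <- conv$table
  long <- tidyr::pivot_longer(
    tb, c("pct95_pmvm_ue", "peak_tens_MPa", "peak_comp_MPa"),
    names_to = "metric", values_to = "value")
  long <- dplyr::mutate(dplyr::group_by(long, .data$metric),
                        rel = .data$value / .data$value[dplyr::n()])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size_mm, y = .data$rel,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "element size (mm)", y = "metric / finest-mesh value",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
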