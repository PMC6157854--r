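# ggplot2 graphics for calibrations and simulated studies.

#' Flow-rate profile of a calibration
#'
#' Personalised flow rate as a function of blood volume, one line per
#' tube voltage.
#'
#' @param cal A `cm_calibration`.
#' @param kv Tube voltages to draw.
#' @param bv_range Blood-volume range in litres.
#' @return A ggplot object.
#' @export
plot_flow_profile <- function(cal, kv = c(70, 80, 90, 120),
                              bv_range = c(3, 7)) {
  grid <- tidyr::expand_grid(
    bv_l = seq(bv_range[1], bv_range[2], length.out = 100),
    kv = kv
  ) |>
    mutate(flow_ml_s = flow_rate(.data$bv_l, .data$kv, cal,
      round = FALSE))
  ggplot2::ggplot(grid, ggplot2::aes(.data$bv_l, .data$flow_ml_s,
    colour = factor(.data$kv))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Blood volume (L)", y = "Flow rate (mL/s)",
      colour = "Tube voltage (kV)") +
    ggplot2::theme_minimal()
}

#' First-pass concentration curve
#'
#' Intravascular contrast concentration over time with its asymptote
#' `F*Ic/CO`.
#'
#' @param params A [pk_params()].
#' @param t_max Right edge of the time axis, seconds.
#' @return A ggplot object.
#' @export
plot_concentration <- function(params = pk_params(), t_max = 30) {
  d <- tibble(t = seq(0, t_max, length.out = 200)) |>
    mutate(conc = cm_concentration(.data$t, params))
  asym <- params$flow_ml_s * params$iodine_mg_ml /
    params$cardiac_output_ml_s
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$conc)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = asym, linetype = "dashed") +
    ggplot2::labs(x = "Time (s)",
      y = "Intravascular concentration (mgI/mL)") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_study Boxplots of personalised flow rate by tube
#'   voltage, sex and scan mode for a simulated study.
#' @param object A `cm_study` object.
#' @exportS3Method ggplot2::autoplot
autoplot.cm_study <- function(object, ...) {
  ggplot2::ggplot(object$protocols,
    ggplot2::aes(factor(.data$kv), .data$flow_ml_s,
      fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "Tube voltage (kV)", y = "Flow rate (mL/s)",
      fill = "Sex") +
    ggplot2::theme_minimal()
}
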