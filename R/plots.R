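# ggplot2 visualizations for waveforms, simulations and cam profiles.

#' Plot a flow waveform
#'
#' @param object A `csf_waveform`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.csf_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$flow_ml_min)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(
      x = "time within cycle (s)",
      y = "flow (ml/min)",
      title = sprintf(
        "Flow waveform, period %.3f s (%s)",
        wf_period(object), attr(object, "sign_convention")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulation result
#'
#' Pressures (ICP, cistern, cranial chamber) and spinal flow over the
#' recorded cycles, as stacked facets.
#'
#' @param object A `csf_simulation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.csf_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("icp_mmHg", "p_cistern_mmHg", "p_cranial_chamber_mmHg", "q_spinal_ml_min"),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(long$series,
    levels = c("q_spinal_ml_min", "icp_mmHg", "p_cistern_mmHg", "p_cranial_chamber_mmHg"),
    labels = c("spinal flow (ml/min)", "ICP (mmHg)", "cistern (mmHg)", "cranial chamber (mmHg)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.4) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Simulated craniospinal dynamics") +
    ggplot2::theme_minimal()
}

#' Per-cycle flow envelope plot
#'
#' Min--max ribbon and mean curve of the spinal flow across recorded cycles
#' on the 0--100% cycle grid (the standard presentation of repeated
#' cardiac-gated flow recordings).
#'
#' @param sim A `csf_simulation`.
#' @return A ggplot.
#' @export
plot_cycle_envelope <- function(sim) {
  env <- cycle_envelope(sim)
  ggplot2::ggplot(env, ggplot2::aes(x = .data$phase_pct)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q_min, ymax = .data$q_max),
      fill = "#74add1", alpha = 0.5
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q_mean), colour = "#2166ac") +
    ggplot2::labs(
      x = "cardiac cycle (%)", y = "spinal flow (ml/min)",
      title = "Spinal CSF flow envelope across cycles"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cam contour
#'
#' @param object A `csf_cam_profile`.
#' @param ... Unused.
#' @return A ggplot (Cartesian contour with the base circle for reference).
#' @exportS3Method ggplot2::autoplot
autoplot.csf_cam_profile <- function(object, ...) {
  theta <- seq(0, 2 * pi, length.out = 361)
  base <- tibble::tibble(
    x_mm = attr(object, "base_radius") * cos(theta),
    y_mm = attr(object, "base_radius") * sin(theta)
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_path(data = base, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = "Cam contour (dashed: base circle)"
    ) +
    ggplot2::theme_minimal()
}
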