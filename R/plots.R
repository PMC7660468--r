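# ggplot2 figures for the main result types.

map_to_df <- function(map, spacing = 1) {
  d <- dim(map)
  tibble::tibble(
    x = rep(((seq_len(d[1]) - 1) + 0.5) * spacing - d[1] * spacing / 2,
            times = d[2]),
    y = rep(((seq_len(d[2]) - 1) + 0.5) * spacing - d[2] * spacing / 2,
            each = d[1]),
    value = as.vector(map)
  )
}

#' Plot an angle or scalar map
#'
#' @param map matrix (NA outside the myocardium).
#' @param spacing pixel spacing (mm).
#' @param title plot title.
#' @param limits optional colour limits (e.g. `c(-90, 90)` for HA).
#' @return A ggplot object.
#' @export
plot_angle_map <- function(map, spacing = 1, title = NULL, limits = NULL) {
  df <- map_to_df(map, spacing)
  ggplot2::ggplot(df[is.finite(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166ac", "#67a9cf", "#f7f7f7", "#ef8a62", "#b2182b"),
      limits = limits) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = title, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cdti_profile <- function(object, ...) {
  df <- object[is.finite(object$median_ha), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_depth, y = .data$median_ha,
                                   colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "normalized transmural depth (endo → epi)",
                  y = "median helix angle (°)",
                  colour = NULL, size = "voxels") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cdti_scout_series <- function(object, ...) {
  y <- if ("normalized" %in% names(object)) "normalized" else "mean"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$td_over_rr, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TD / RR", y = paste(y, "trace signal")) +
    ggplot2::theme_minimal()
}

#' Plot the effective gradient waveform
#'
#' @param w a `cdti_waveform`.
#' @param dt sampling interval (ms).
#' @return A ggplot object.
#' @export
plot_waveform <- function(w, dt = 0.01) {
  df <- gradient_samples(w, dt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time from excitation (ms)",
                  y = "effective gradient (mT/m)") +
    ggplot2::theme_minimal()
}

#' Per-phase metric distribution plot (study-level)
#'
#' Boxplots with per-subject points, one box per cardiac phase, in the
#' style of the angle/invariant statistics figures.
#'
#' @param df data frame with one row per subject-phase.
#' @param value metric column (tidy-eval).
#' @param phase phase column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_phase_stats <- function(df, value, phase) {
  ggplot2::ggplot(df, ggplot2::aes(x = {{ phase }}, y = {{ value }})) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::theme_minimal()
}
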