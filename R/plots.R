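# ggplot2 methods for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   geom_step labs scale_fill_viridis_c theme_minimal facet_wrap
NULL

#' Plot a trial-averaged spectrum, optionally with its aperiodic fit
#'
#' @param object A `clop_spectrum`.
#' @param fit Optional `clop_aperiodic_fit` drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clop_spectrum
#' @export
autoplot.clop_spectrum <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$frequency_hz, y = .data$power_db)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "power (dB)",
         title = sprintf("%s spectrum, %d trials",
                         attr(object, "mode"), attr(object, "n_trials"))) +
    theme_minimal()
  if (!is.null(fit)) {
    df <- tibble(frequency_hz = object$frequency_hz,
                 power_db = predict(fit, object$frequency_hz))
    p <- p + geom_line(data = df, linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a z-score spectrogram as a raster
#'
#' @param object A `clop_zscore_map`.
#' @param zlim Clipping limits for the colour scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clop_zscore_map
#' @export
autoplot.clop_zscore_map <- function(object, zlim = c(0, 10), ...) {
  df <- tidy.clop_zscore_map(object)
  df$z <- pmin(pmax(df$z, zlim[1]), zlim[2])
  ggplot(df, aes(x = .data$time_s, y = .data$frequency_hz, fill = .data$z)) +
    geom_raster() +
    scale_fill_viridis_c(name = "z") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot per-animal cumulative chloride distributions with the group mean
#'
#' @param object A `clop_group_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clop_group_summary
#' @export
autoplot.clop_group_summary <- function(object, ...) {
  df <- object$ecdf
  ggplot(df[df$animal_id != ".group_mean", ],
         aes(x = .data$value, y = .data$F, group = .data$animal_id)) +
    geom_line(alpha = 0.4) +
    geom_line(data = df[df$animal_id == ".group_mean", ],
              linewidth = 1.2, colour = "black") +
    facet_wrap(~condition) +
    labs(x = object$value, y = "cumulative fraction") +
    theme_minimal()
}

#' Plot a binned actogram
#'
#' @param object A `clop_actogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clop_actogram
#' @export
autoplot.clop_actogram <- function(object, ...) {
  ggplot(object, aes(x = .data$zt_h, y = .data$distance_cm)) +
    geom_col(width = attr(object, "bin_s") / 3600) +
    labs(x = "zeitgeber time (h)", y = "distance per bin (cm)") +
    theme_minimal()
}

#' Plot a cumulative pathological-activity curve
#'
#' @param object A `clop_cumcurve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clop_cumcurve
#' @export
autoplot.clop_cumcurve <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$cumulative)) +
    geom_step() +
    labs(x = "time (s)",
         y = sprintf("cumulative activity (%s)", attr(object, "method"))) +
    theme_minimal()
}
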