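# ggplot2 rendering for the main result types.

#' @export
autoplot.mt_spectrum <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (dB re uV²/Hz)")
  if (!is.null(fit)) {
    f <- object$frequency[object$frequency > 0]
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(frequency = f, power_db = fitted_db(fit, f)),
      linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' @export
autoplot.coherence_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude-squared coherence")
}

#' @export
autoplot.eeg_spectrogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$frequency,
                                       fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)")
}

#' @export
autoplot.topo_map <- function(object, ...) {
  grid <- attr(object, "grid")
  if (is.null(grid)) {
    object <- interpolate_topomap(object)
    grid <- attr(object, "grid")
  }
  ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = grid, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)
    ) +
    ggplot2::geom_point(
      data = object, ggplot2::aes(x = .data$x, y = .data$y), size = 0.8
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @export
autoplot.evoked_average <- function(object, ...) {
  long <- tibble::tibble(
    channel = rep(rownames(object$data) %||% object$channels, times = ncol(object$data)),
    time = rep(object$times * 1000, each = nrow(object$data)),
    value = as.vector(object$data)
  )
  gfp <- global_field_power(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(
      data = tibble::tibble(time = gfp$time * 1000, value = gfp$gfp, channel = "GFP"),
      colour = "red"
    ) +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (uV)")
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(y = c(object$bias, object$loa_lower, object$loa_upper),
                       kind = c("bias", "LoA", "LoA"))
  ggplot2::ggplot(df) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$y, linetype = .data$kind)) +
    ggplot2::labs(y = "Difference (subscalp - scalp)", x = NULL)
}

#' Bland-Altman scatter plot for paired measurements
#'
#' @param data Paired-measurement data frame.
#' @param ba Optional precomputed [bland_altman()] result.
#' @return A ggplot object (mean vs difference with bias and limits of
#'   agreement).
#' @export
plot_bland_altman <- function(data, ba = NULL) {
  ba <- ba %||% bland_altman(data)
  df <- tibble::tibble(
    m = (data$value_subscalp + data$value_scalp) / 2,
    d = data$value_subscalp - data$value_scalp
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Pair mean", y = "Difference (subscalp - scalp)")
}
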