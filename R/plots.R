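#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster-and-LFP overview of a simulation
#'
#' Spike raster of all populations over time with the global PY LFP below,
#' the standard at-a-glance view of stage transitions.
#'
#' @param object A `tc_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_sim <- function(object, ...) {
  sp <- dplyr::mutate(object$spikes,
    pop = factor(.data$pop, levels = c("RE", "TC", "IN", "PY"))
  )
  lfp <- compute_lfp(object, "all", discard_s = 0)
  p1 <- ggplot2::ggplot(sp, ggplot2::aes(.data$t_ms / 1000, .data$cell)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pop), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "cell") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(lfp, ggplot2::aes(.data$time_s, .data$ch1)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "LFP (mV)") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(3, 1)))
  }
  p1
}

#' Plot an LFP series
#'
#' @param object An `lfp_series`.
#' @param ... Unused.
#' @return A ggplot object (channels stacked).
#' @export
autoplot.lfp_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
    names_to = "channel", values_to = "v"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$v)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "mean membrane voltage (mV)") +
    ggplot2::theme_minimal()
}

#' Feature-space view of a regime-cluster model
#'
#' Delta power against spindle power, colored by cluster assignment, with
#' component means overplotted.
#'
#' @param object A `state_cluster_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_cluster_model <- function(object, ...) {
  d <- tibble::as_tibble(as.data.frame(object$data))
  d$cluster <- factor(object$assignment[!is.na(object$assignment)])
  mu <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_power, .data$spindle_power)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$cluster), alpha = 0.7) +
    ggplot2::geom_point(
      data = mu,
      ggplot2::aes(.data$delta_power, .data$spindle_power),
      shape = 8, size = 3
    ) +
    ggplot2::labs(
      x = if (object$log_power) "log10 delta power" else "delta power",
      y = if (object$log_power) "log10 spindle power" else "spindle power"
    ) +
    ggplot2::theme_minimal()
}

#' Sliding-window spectrogram of an LFP channel
#'
#' @param lfp An `lfp_series`.
#' @param window_s,slide_s Window length and step (s).
#' @param fmax Highest frequency plotted (Hz).
#' @param channel Channel name (default first).
#' @return A ggplot object (log10 power).
#' @export
plot_spectrogram <- function(lfp, window_s = 2, slide_s = 0.5, fmax = 20,
                             channel = NULL) {
  fs <- lfp_rate(lfp)
  if (is.null(channel)) channel <- lfp_channels(lfp)[1]
  x <- lfp[[channel]]
  nwin <- floor(window_s * fs)
  step <- max(1, floor(slide_s * fs))
  starts <- seq(1, length(x) - nwin + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  f <- (seq_len(nwin) - 1) * fs / nwin
  keep <- f > 0 & f <= fmax
  d <- purrr::map_dfr(starts, function(s) {
    seg <- x[s:(s + nwin - 1)]
    spec <- Mod(fft((seg - mean(seg)) * w))^2
    tibble::tibble(
      time_s = lfp$time_s[1] + (s - 1 + nwin / 2) / fs,
      freq_hz = f[keep], power = spec[keep]
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$freq_hz,
    fill = log10(.data$power + 1e-12)
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
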