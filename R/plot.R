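# Diagnostic plots (ggplot2).

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_rect labs facet_wrap scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot dF/F0 traces with detections
#'
#' Stacked per-neuron traces; detected spikes are marked above each trace
#' and plateau intervals shaded.
#'
#' @param traces dF/F0 tibble (`neuron_id`, `time_s`, `dff`).
#' @param spikes optional spike tibble.
#' @param plateaus optional plateau tibble.
#' @param spacing vertical offset between neurons (percent dF/F0).
#' @return a ggplot.
#' @export
plot_traces <- function(traces, spikes = NULL, plateaus = NULL,
                        spacing = 15) {
  traces <- dplyr::mutate(traces,
    y = .data$dff + (as.integer(factor(.data$neuron_id)) - 1) * spacing
  )
  p <- ggplot(traces, aes(.data$time_s, .data$y, group = .data$neuron_id)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = sprintf("dF/F0 (%%, offset %g)", spacing)) +
    theme_minimal()
  if (!is.null(plateaus) && nrow(plateaus)) {
    lv <- levels(factor(traces$neuron_id))
    pl <- dplyr::mutate(plateaus,
      ymin = (match(as.character(.data$neuron_id), lv) - 1) * spacing - 5,
      ymax = .data$ymin + spacing - 5
    )
    p <- p + geom_rect(
      data = pl,
      aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = .data$ymin, ymax = .data$ymax
      ),
      inherit.aes = FALSE, alpha = 0.2, fill = "steelblue"
    )
  }
  if (!is.null(spikes) && nrow(spikes)) {
    lv <- levels(factor(traces$neuron_id))
    sp <- dplyr::mutate(spikes,
      y = (match(as.character(.data$neuron_id), lv) - 1) * spacing + 12
    )
    p <- p + geom_point(
      data = sp, aes(.data$time_s, .data$y),
      inherit.aes = FALSE, shape = 4, size = 0.7, colour = "red"
    )
  }
  p
}

#' @export
#' @rdname autoplot_voltrace
#' @method autoplot vi_roiset
autoplot.vi_roiset <- function(object, ...) {
  d <- object$dim
  n <- ncol(object$spatial_filters)
  df <- purrr::map_dfr(seq_len(n), function(i) {
    f <- object$spatial_filters[, i]
    tibble(
      roi = i,
      row = rep(seq_len(d[1]), d[2]),
      col = rep(seq_len(d[2]), each = d[1]),
      weight = f / max(abs(f))
    )
  })
  ggplot(df, aes(.data$col, .data$row, fill = .data$weight)) +
    geom_raster() +
    scale_fill_viridis_c() +
    facet_wrap(~roi) +
    labs(x = NULL, y = NULL, title = "ICA spatial filters") +
    theme_minimal()
}

#' Autoplot methods for voltrace objects
#'
#' `vi_roiset`: facetted spatial-filter maps. `vi_waveforms`: aligned
#' per-spike segments with the mean waveform overlaid. `vi_run`: stacked
#' traces with detections (see [plot_traces()]).
#'
#' @param object the object to plot.
#' @param ... unused.
#' @param max_segments spaghetti cap for waveform plots.
#' @return a ggplot.
#' @name autoplot_voltrace
NULL

#' @export
#' @rdname autoplot_voltrace
#' @method autoplot vi_waveforms
autoplot.vi_waveforms <- function(object, max_segments = 200, ...) {
  ns <- nrow(object$segments)
  if (!ns) abort("no waveform segments to plot")
  pick <- seq_len(min(ns, max_segments))
  t_ms <- (seq_len(ncol(object$segments)) - object$peak_index) * 1000 /
    object$frame_rate
  df <- purrr::map_dfr(pick, function(i) {
    tibble(spike = i, time_ms = t_ms, dff = object$segments[i, ])
  })
  ggplot(df, aes(.data$time_ms, .data$dff, group = .data$spike)) +
    geom_line(alpha = 0.15, linewidth = 0.2) +
    geom_line(
      data = mean_waveform(object),
      aes(.data$time_ms, .data$dff),
      inherit.aes = FALSE, colour = "red", linewidth = 0.8
    ) +
    labs(x = "time from peak (ms)", y = "dF/F0 (%)") +
    theme_minimal()
}

#' @export
#' @rdname autoplot_voltrace
#' @method autoplot vi_run
autoplot.vi_run <- function(object, ...) {
  plot_traces(object$traces, object$spikes, object$plateaus)
}
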