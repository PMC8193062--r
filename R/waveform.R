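# Per-spike waveform segments and shape metrics.

#' Extract peak-aligned AP waveform segments
#'
#' Cuts a window (default 300 ms) out of the dF/F0 trace around every
#' detected spike, centered on the trace-sample peak, so all segments share
#' one peak index (integer alignment; no resampling). Spikes closer than
#' half a window to either edge are excluded and counted.
#'
#' @param data tibble with `time_s`, `dff` (optionally `neuron_id`).
#' @param spikes spike tibble from [detect_spikes()] (needs `frame`).
#' @param window_ms window length (default 300 ms).
#' @param baseline_ms length of the segment-edge windows used as local
#'   baseline by the shape metrics (default 50 ms).
#' @return object of class `vi_waveforms`: list with `segments` (spike x
#'   sample matrix), `peak_index`, `frame_rate`, `metrics` (per-spike tibble
#'   with `neuron_id`, `spike_time_s`, `fwhm_ms`, `amplitude`, `rise_ms`,
#'   `decay_ms`, `overlapping`, `valid`), `n_edge_excluded`.
#' @export
extract_waveforms <- function(data, spikes, window_ms = 300,
                              baseline_ms = 50) {
  stopifnot(is.data.frame(spikes))
  data_split <- split_by_neuron(data)
  fr <- frame_rate_of(data)
  half <- round(window_ms * fr / 2000)
  len <- 2L * half + 1L
  seg_list <- list()
  meta <- list()
  n_edge <- 0L
  spike_split <- split_by_neuron(spikes)
  for (id in names(spike_split)) {
    sp <- spike_split[[id]]
    df <- data_split[[as.character(id)]]
    if (is.null(df)) next
    s <- df$dff
    for (j in seq_len(nrow(sp))) {
      ctr <- sp$frame[j]
      if (ctr - half < 1 || ctr + half > length(s)) {
        n_edge <- n_edge + 1L
        next
      }
      seg_list[[length(seg_list) + 1L]] <- s[(ctr - half):(ctr + half)]
      gap_prev <- if (j > 1) sp$time_s[j] - sp$time_s[j - 1] else Inf
      gap_next <- if (j < nrow(sp)) sp$time_s[j + 1] - sp$time_s[j] else Inf
      meta[[length(meta) + 1L]] <- tibble(
        neuron_id = sp$neuron_id[j], spike_time_s = sp$time_s[j],
        overlapping = min(gap_prev, gap_next) < window_ms / 2000
      )
    }
  }
  if (!length(seg_list)) {
    segments <- matrix(numeric(0), 0, len)
    metrics <- tibble(
      neuron_id = integer(0), spike_time_s = numeric(0),
      overlapping = logical(0), fwhm_ms = numeric(0),
      amplitude = numeric(0), rise_ms = numeric(0), decay_ms = numeric(0),
      valid = logical(0)
    )
  } else {
    segments <- do.call(rbind, seg_list)
    metrics <- dplyr::bind_rows(meta)
    shape <- purrr::map_dfr(
      seq_len(nrow(segments)),
      function(i) waveform_params(segments[i, ], fr, baseline_ms)
    )
    metrics <- dplyr::bind_cols(metrics, shape)
  }
  structure(
    list(
      segments = segments, peak_index = half + 1L, frame_rate = fr,
      window_ms = window_ms, baseline_ms = baseline_ms,
      metrics = metrics, n_edge_excluded = n_edge
    ),
    class = "vi_waveforms"
  )
}

#' @export
print.vi_waveforms <- function(x, ...) {
  cat(sprintf(
    "<vi_waveforms> %d segments of %d samples (%g ms window), %d edge-excluded\n",
    nrow(x$segments), ncol(x$segments), x$window_ms, x$n_edge_excluded
  ))
  invisible(x)
}

#' Mean AP waveform across aligned segments
#'
#' @param waveforms a [extract_waveforms()] result.
#' @return tibble `time_ms` (0 at the aligned peak), `dff`.
#' @export
mean_waveform <- function(waveforms) {
  stopifnot(inherits(waveforms, "vi_waveforms"))
  if (!nrow(waveforms$segments)) abort("no segments")
  m <- colMeans(waveforms$segments)
  tibble(
    time_ms = (seq_along(m) - waveforms$peak_index) * 1000 /
      waveforms$frame_rate,
    dff = m
  )
}

segment_baseline <- function(segment, frame_rate, baseline_ms) {
  nb <- max(1L, round(baseline_ms * frame_rate / 1000))
  nb <- min(nb, floor(length(segment) / 3))
  median(c(head(segment, nb), tail(segment, nb)))
}

#' Full width at half maximum of one AP segment
#'
#' Baseline is the median of the first and last `baseline_ms` of the
#' segment; half maximum is halfway between baseline and the peak; crossing
#' times on both flanks are linearly interpolated between samples, giving
#' sub-frame resolution. FWHM is invariant to adding a constant or scaling
#' by a positive factor.
#'
#' @param segment numeric dF/F0 vector containing one dominant peak.
#' @param frame_rate sampling rate in Hz.
#' @param baseline_ms edge-window length used for the baseline.
#' @return FWHM in milliseconds, or `NA` if a flank never crosses half
#'   maximum (truncated waveform).
#' @examples
#' t <- seq(-150, 150, by = 2)
#' seg <- 10 * exp(-t^2 / (2 * 5^2)) # Gaussian sigma 5 ms
#' compute_fwhm(seg, 500) # ~11.77
#' @export
compute_fwhm <- function(segment, frame_rate, baseline_ms = 50) {
  p <- fwhm_crossings(segment, frame_rate, baseline_ms)
  if (!p$valid) {
    return(NA_real_)
  }
  p$right_ms - p$left_ms
}

# Shared flank-crossing finder: returns interpolated half-max crossing times
# (ms, relative to segment start) around the global peak.
fwhm_crossings <- function(segment, frame_rate, baseline_ms = 50) {
  dt_ms <- 1000 / frame_rate
  base <- segment_baseline(segment, frame_rate, baseline_ms)
  pk <- which.max(segment)
  amp <- segment[pk] - base
  if (amp <= 0) {
    return(list(valid = FALSE))
  }
  half <- base + amp / 2
  left <- NA_real_
  for (i in (if (pk > 1) seq(pk - 1, 1) else integer(0))) {
    if (segment[i] < half) {
      left <- interp_crossing(
        (i - 1) * dt_ms, i * dt_ms, segment[i], segment[i + 1], half
      )
      break
    }
  }
  right <- NA_real_
  if (pk < length(segment)) {
    for (i in seq(pk + 1, length(segment))) {
      if (segment[i] < half) {
        right <- interp_crossing(
          (i - 2) * dt_ms, (i - 1) * dt_ms, segment[i - 1], segment[i], half
        )
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    return(list(valid = FALSE))
  }
  list(
    valid = TRUE, left_ms = left, right_ms = right,
    peak_index = pk, baseline = base, amplitude = amp
  )
}

#' Shape parameters of one AP segment
#'
#' Amplitude (peak minus edge-window baseline), 10-90% rise time before the
#' peak, 90-10% decay time after it, and the FWHM, all with linearly
#' interpolated level crossings. Degenerate segments (no peak above
#' baseline, or a flank that never returns) are flagged `valid = FALSE`.
#'
#' @inheritParams compute_fwhm
#' @return one-row tibble: `fwhm_ms`, `amplitude`, `rise_ms`, `decay_ms`,
#'   `valid`.
#' @export
waveform_params <- function(segment, frame_rate, baseline_ms = 50) {
  dt_ms <- 1000 / frame_rate
  p <- fwhm_crossings(segment, frame_rate, baseline_ms)
  bad <- tibble(
    fwhm_ms = NA_real_, amplitude = NA_real_,
    rise_ms = NA_real_, decay_ms = NA_real_, valid = FALSE
  )
  if (!p$valid) {
    return(bad)
  }
  base <- p$baseline
  amp <- p$amplitude
  pk <- p$peak_index
  level_cross <- function(from, to, level) {
    # first crossing of `level` walking from `from` towards `to`
    step <- if (to >= from) 1L else -1L
    idx <- seq(from, to, by = step)
    for (i in idx[-1]) {
      prev <- i - step
      if ((step > 0 && segment[i] < level) ||
        (step < 0 && segment[i] < level)) {
        lo <- min(i, prev)
        return(interp_crossing(
          (lo - 1) * dt_ms, lo * dt_ms, segment[lo], segment[lo + 1], level
        ))
      }
    }
    NA_real_
  }
  t10_pre <- level_cross(pk, 1, base + 0.1 * amp)
  t90_pre <- level_cross(pk, 1, base + 0.9 * amp)
  t90_post <- level_cross(pk, length(segment), base + 0.9 * amp)
  t10_post <- level_cross(pk, length(segment), base + 0.1 * amp)
  tibble(
    fwhm_ms = p$right_ms - p$left_ms,
    amplitude = amp,
    rise_ms = if (is.na(t10_pre) || is.na(t90_pre)) {
      NA_real_
    } else {
      t90_pre - t10_pre
    },
    decay_ms = if (is.na(t10_post) || is.na(t90_post)) {
      NA_real_
    } else {
      t10_post - t90_post
    },
    valid = TRUE
  )
}
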