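# broom-style accessors.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname vi_tidiers
#' @method tidy vi_waveforms
#' @param x a fitted/derived voltrace object.
#' @param ... unused.
tidy.vi_waveforms <- function(x, ...) x$metrics

#' Tidy and summarise voltrace objects
#'
#' `tidy()` returns the per-element table of a result (per-spike waveform
#' metrics, per-ROI quality scores, per-component variance explained,
#' per-neuron firing statistics); `glance()` returns a one-row summary of a
#' pipeline run.
#'
#' @name vi_tidiers
#' @return a tibble.
NULL

#' @export
#' @rdname vi_tidiers
#' @method tidy vi_roiset
tidy.vi_roiset <- function(x, ...) {
  tibble(
    roi = seq_len(ncol(x$spatial_filters)),
    skew_spatial = x$skew_spatial,
    skew_temporal = x$skew_temporal,
    mask_px = if (is.null(x$masks)) NA_integer_ else lengths(x$masks)
  )
}

#' @export
#' @rdname vi_tidiers
#' @method tidy vi_pca
tidy.vi_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$var_explained),
    var_explained = x$var_explained
  )
}

#' @export
#' @rdname vi_tidiers
#' @method tidy vi_run
tidy.vi_run <- function(x, ...) x$stats

#' @export
#' @rdname vi_tidiers
#' @method glance vi_run
glance.vi_run <- function(x, ...) {
  wf <- x$waveforms$metrics
  ok <- wf$valid & !is.na(wf$fwhm_ms)
  tibble(
    n_rois = length(x$roiset$masks),
    n_spikes = nrow(x$spikes),
    n_bursts = nrow(x$bursts),
    mean_firing_rate_hz = mean(x$stats$firing_rate_hz),
    mean_bursting_rate_per_min = mean(x$stats$bursting_rate_per_min),
    mean_fwhm_ms = if (any(ok)) mean(wf$fwhm_ms[ok]) else NA_real_,
    duration_s = x$stats$duration_s[1]
  )
}
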