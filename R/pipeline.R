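# End-to-end orchestration: movie -> traces -> spikes -> events -> stats.

#' Analysis settings for the pipeline
#'
#' Collects the tunable analysis parameters with their defaults:
#' spatial Gaussian sigma 1 px; temporal moving average of 3 frames applied
#' to the detection trace (6 ms at 500 Hz, kept short so AP waveforms are
#' not widened; waveform metrics are measured on the unsmoothed trace);
#' segmentation runs on a copy temporally binned by `seg_bin_frames` with
#' `3 x` the expected neuron count of principal components (capped at
#' `max_components`); ICs with temporal skewness below `quality_min_skew`
#' are discarded as noise; NEO threshold 3 SD; hard minimum ISI 20 ms;
#' 300 ms waveform windows.
#'
#' @param spatial_sigma_px,detect_smooth_frames movie/trace smoothing.
#' @param seg_bin_frames temporal binning factor for segmentation.
#' @param components_per_neuron,max_components PCA sizing.
#' @param ica_mu spatio-temporal ICA weight.
#' @param quality_min_skew minimum temporal skewness for an IC to count as
#'   a neuron.
#' @param mask_threshold filter-to-mask level, fraction of the maximum.
#' @param k_sd NEO threshold in SDs.
#' @param min_isi_ms detector refractory bound.
#' @param detect_highpass_ms running-median slow-envelope subtraction ahead
#'   of NEO (see [detect_spikes()]); removes plateau offsets, to which the
#'   energy operator is not invariant.
#' @param window_ms,baseline_ms waveform window and edge-baseline length.
#' @param plateau_cutoff_hz,plateau_k_sd,plateau_min_ms plateau detector.
#' @param burst_max_mean_isi_ms burst criterion.
#' @param detrend divide out a fitted bleaching exponential before dF/F0
#'   analysis (off by default; shuttered acquisitions show virtually no
#'   bleaching).
#' @return named list of settings.
#' @export
pipeline_options <- function(spatial_sigma_px = 1,
                             detect_smooth_frames = 3L,
                             seg_bin_frames = 3L,
                             components_per_neuron = 3L,
                             max_components = 60L,
                             ica_mu = 0.5,
                             quality_min_skew = 0.2,
                             mask_threshold = 0.5,
                             k_sd = 3,
                             min_isi_ms = 20,
                             detect_highpass_ms = 80,
                             window_ms = 300,
                             baseline_ms = 50,
                             plateau_cutoff_hz = 5,
                             plateau_k_sd = 3,
                             plateau_min_ms = 200,
                             burst_max_mean_isi_ms = 250,
                             detrend = FALSE) {
  as.list(environment())
}

#' Run the full voltage-imaging analysis pipeline
#'
#' Stages: (optional) simulation; spatial denoising; PCA/ICA segmentation on
#' a temporally binned copy; weighted trace extraction and conversion to
#' percent dF/F0; NEO spike detection on a lightly smoothed copy of each
#' trace; AP waveform metrics on the unsmoothed trace; plateau detection;
#' burst and singlet/doublet/triplet classification; per-neuron firing
#' statistics. Deterministic given the config seed.
#'
#' @param config a [sim_config()]/[sim_preset()] describing the recording to
#'   simulate, or `NULL` when `movie` is given.
#' @param movie an existing [vi_movie()] to analyse instead of simulating.
#' @param expected_neurons neuron count used to size the PCA/ICA (taken
#'   from `config` when simulating).
#' @param options a [pipeline_options()] list.
#' @param out_dir if non-`NULL`, CSV/JSON outputs are written there.
#' @param verbose log each stage with counts.
#' @return `vi_run` list: `traces` (dF/F0 tibble), `roiset`, `spikes`,
#'   `waveforms`, `plateaus`, `bursts`, `events`, `stats`, `truth` (when
#'   simulated), `manifest`.
#' @export
run_pipeline <- function(config = NULL, movie = NULL, expected_neurons = NULL,
                         options = pipeline_options(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  truth <- NULL
  if (is.null(movie)) {
    if (is.null(config)) abort("supply either `config` or `movie`")
    say("simulate: %d neurons, %g s @ %g Hz", config$n_neurons,
      config$duration_s, config$frame_rate)
    sim <- simulate_movie(config)
    movie <- sim$movie
    truth <- sim$truth
    sim <- NULL
    expected_neurons <- expected_neurons %||% config$n_neurons
  }
  if (is.null(expected_neurons)) {
    abort("`expected_neurons` is required when analysing a recorded movie")
  }
  seed <- if (!is.null(config)) config$seed else 1L
  opt <- options
  fr <- attr(movie, "frame_rate")

  say("segment: binning x%d, spatial sigma %g px", opt$seg_bin_frames,
    opt$spatial_sigma_px)
  seg_movie <- bin_movie(movie, opt$seg_bin_frames)
  seg_movie <- spatiotemporal_filter(seg_movie,
    spatial_sigma_px = opt$spatial_sigma_px, temporal_window = 1L
  )
  n_comp <- min(
    opt$components_per_neuron * expected_neurons,
    opt$max_components
  )
  pca <- pca_reduce(seg_movie, n_comp, expected_neurons = expected_neurons)
  rm(seg_movie)
  gc(FALSE)
  roiset <- ica_unmix(pca, n_ics = expected_neurons, mu = opt$ica_mu,
    seed = substream_seed(seed, 700))
  rm(pca)
  gc(FALSE)
  roiset <- filters_to_masks(roiset, opt$mask_threshold)
  ok <- roiset$skew_temporal >= opt$quality_min_skew
  roiset$spatial_filters <- roiset$spatial_filters[, ok, drop = FALSE]
  roiset$temporal_ics <- roiset$temporal_ics[, ok, drop = FALSE]
  roiset$skew_spatial <- roiset$skew_spatial[ok]
  roiset$skew_temporal <- roiset$skew_temporal[ok]
  roiset$masks <- roiset$masks[ok]
  say("segment: %d ROIs pass quality (of %d ICs)", sum(ok), length(ok))
  if (!length(roiset$masks)) abort("segmentation returned no usable ROIs")

  say("extract: weighted traces + dF/F0")
  traces <- extract_traces(movie, roiset, weighting = "filter")
  duration_s <- n_frames(movie) / fr
  movie_fov <- fov_dim(movie)
  movie_frames <- n_frames(movie)
  rm(movie)
  gc(FALSE)
  if (isTRUE(opt$detrend)) {
    traces <- dplyr::bind_rows(lapply(split_by_neuron(traces), function(df) {
      raw <- tibble(time_s = df$time_s, f = df$f0 * (1 + df$dff / 100))
      det <- detrend_bleach(raw)
      df$dff <- 100 * (det$f - df$f0) / df$f0
      df
    }))
  }

  say("detect: NEO %g SD, min ISI %g ms", opt$k_sd, opt$min_isi_ms)
  spikes <- detect_spikes(traces,
    k_sd = opt$k_sd, min_isi_ms = opt$min_isi_ms,
    smooth_window = opt$detect_smooth_frames,
    highpass_ms = opt$detect_highpass_ms
  )
  say("detect: %d spikes on %d neurons", nrow(spikes),
    length(unique(spikes$neuron_id)))

  waveforms <- extract_waveforms(traces, spikes,
    window_ms = opt$window_ms, baseline_ms = opt$baseline_ms
  )
  plateaus <- detect_plateaus(traces,
    lowpass_cutoff_hz = opt$plateau_cutoff_hz,
    k_sd = opt$plateau_k_sd, min_duration_ms = opt$plateau_min_ms
  )
  bursts <- detect_bursts(spikes,
    max_mean_isi_ms = opt$burst_max_mean_isi_ms
  )
  events <- classify_events(spikes, bursts, plateaus,
    gap_ms = opt$burst_max_mean_isi_ms
  )
  stats_tbl <- compute_firing_stats(spikes, bursts, duration_s,
    neuron_ids = seq_along(roiset$masks)
  )
  say("events: %d bursts, %d events", nrow(bursts), nrow(events))

  manifest <- list(
    package_version = as.character(utils::packageVersion("voltrace")),
    seed = seed,
    frame_rate = fr, n_frames = movie_frames,
    fov = movie_fov, expected_neurons = expected_neurons,
    options = opt,
    config = if (!is.null(config)) {
      config[!vapply(config, is.function, TRUE)]
    },
    counts = list(
      rois = length(roiset$masks), spikes = nrow(spikes),
      bursts = nrow(bursts), events = nrow(events),
      plateaus = nrow(plateaus)
    ),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")
  )
  run <- structure(
    list(
      traces = traces, roiset = roiset, spikes = spikes,
      waveforms = waveforms, plateaus = plateaus, bursts = bursts,
      events = events, stats = stats_tbl, truth = truth,
      manifest = manifest
    ),
    class = "vi_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.vi_run <- function(x, ...) {
  cat(sprintf(
    "<vi_run> %d ROIs, %d spikes, %d bursts over %g s\n",
    length(x$roiset$masks), nrow(x$spikes), nrow(x$bursts),
    x$stats$duration_s[1] %||% NA
  ))
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits `spikes.csv` (`neuron_id, spike_time_s, neo_score`),
#' `events.csv`, `stats.csv` (one row per neuron), `waveform_metrics.csv`,
#' `plateaus.csv` and `manifest.json` into `dir`.
#'
#' @param run a `vi_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- run$spikes
  write.csv(
    data.frame(
      neuron_id = sp$neuron_id, spike_time_s = sp$time_s,
      neo_score = sp$neo_score
    ),
    file.path(dir, "spikes.csv"),
    row.names = FALSE
  )
  write.csv(run$events, file.path(dir, "events.csv"), row.names = FALSE)
  stats_flat <- dplyr::select(
    run$stats, -dplyr::any_of(c("isi", "ibi", "burst_durations"))
  )
  write.csv(stats_flat, file.path(dir, "stats.csv"), row.names = FALSE)
  write.csv(run$waveforms$metrics, file.path(dir, "waveform_metrics.csv"),
    row.names = FALSE
  )
  write.csv(run$plateaus, file.path(dir, "plateaus.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
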