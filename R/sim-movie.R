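# Rendering: ground-truth dF/F0 traces -> camera counts.

# Plateau depolarization: flat top with raised-cosine ramps so the slow
# event carries no spurious high-frequency energy (an instantaneous step
# would register in the nonlinear energy operator like a spike; real plateau
# onsets take tens of milliseconds).
plateau_waveform <- function(times, start_s, end_s, amplitude, ramp_s = 0.1) {
  y <- numeric(length(times))
  up <- times >= start_s & times < start_s + ramp_s
  top <- times >= start_s + ramp_s & times <= end_s - ramp_s
  down <- times > end_s - ramp_s & times <= end_s
  y[up] <- 0.5 * (1 - cos(pi * (times[up] - start_s) / ramp_s))
  y[top] <- 1
  y[down] <- 0.5 * (1 - cos(pi * (end_s - times[down]) / ramp_s))
  amplitude * y
}

# Ground-truth dF/F0 trace for one neuron at the frame times.
truth_dff_trace <- function(times, spikes, fwhm_ms, amplitude, ap_shape,
                            plateaus = NULL, plateau_amplitude = 0) {
  dff <- numeric(length(times))
  if (length(spikes)) {
    dt <- times[2] - times[1]
    half_lo <- 1.6 * fwhm_ms / 1000
    half_hi <- 3.2 * fwhm_ms / 1000
    for (s in spikes) {
      i0 <- max(1L, floor((s - half_lo) / dt) + 1L)
      i1 <- min(length(times), ceiling((s + half_hi) / dt) + 1L)
      idx <- i0:i1
      dff[idx] <- dff[idx] +
        ap_kernel_value((times[idx] - s) * 1000, fwhm_ms, amplitude, ap_shape)
    }
  }
  if (!is.null(plateaus) && nrow(plateaus)) {
    for (j in seq_len(nrow(plateaus))) {
      dff <- dff + plateau_waveform(
        times, plateaus$start_s[j], plateaus$end_s[j], plateau_amplitude
      )
    }
  }
  dff
}

simulate_plateaus <- function(rate_per_min, duration_s, plateau_duration_s,
                              seed) {
  onsets <- with_seed(seed, poisson_times(rate_per_min / 60, duration_s))
  if (!length(onsets)) {
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  iv <- tibble(start_s = onsets, end_s = onsets + plateau_duration_s)
  # merge overlaps so intervals are disjoint
  keep <- list(c(iv$start_s[1], iv$end_s[1]))
  for (j in seq_len(nrow(iv))[-1]) {
    last <- keep[[length(keep)]]
    if (iv$start_s[j] <= last[2]) {
      keep[[length(keep)]][2] <- max(last[2], iv$end_s[j])
    } else {
      keep[[length(keep) + 1]] <- c(iv$start_s[j], iv$end_s[j])
    }
  }
  m <- do.call(rbind, keep)
  tibble(start_s = m[, 1], end_s = pmin(m[, 2], duration_s))
}

#' Render a movie from ground truth
#'
#' Converts per-neuron dF/F0 traces into camera counts:
#' `counts = background + baseline * sum_n footprint_n * (1 + dff_n/100) *
#' exp(-t/bleach_tau)`, with optional Poisson shot noise and 16-bit clipping.
#' Without noise, counts are rounded to integers (16-bit quantization).
#'
#' @param truth ground-truth list as built by [simulate_movie()] (fields
#'   `footprints`, `dff` matrix `n x T`).
#' @param config a [sim_config()].
#' @return a `vi_movie` of integer counts.
#' @export
render_movie <- function(truth, config) {
  fov <- config$fov_shape
  n_t <- round(config$duration_s * config$frame_rate)
  npix <- prod(fov)
  Fm <- matrix(truth$footprints, npix, config$n_neurons)
  D <- truth$dff
  stopifnot(ncol(D) == n_t)
  times <- (seq_len(n_t) - 1) / config$frame_rate
  bleach <- if (is.finite(config$bleach_tau_s)) {
    exp(-times / config$bleach_tau_s)
  } else {
    rep(1, n_t)
  }
  # conservative overflow check: brightest pixel at the hottest frame
  max_w <- max(Fm %*% (1 + apply(D, 1, max) / 100))
  if (config$background_counts + config$baseline_counts * max_w > 65535) {
    abort("expected counts overflow 16-bit: lower `baseline_counts`")
  }
  out <- array(0L, c(fov[1], fov[2], n_t))
  chunk <- 5000L
  noise_seed <- substream_seed(config$seed, 990)
  with_seed(noise_seed, {
    for (start in seq(1L, n_t, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n_t)
      lam <- config$baseline_counts *
        (Fm %*% (1 + D[, idx, drop = FALSE] / 100))
      lam <- sweep(lam, 2, bleach[idx], `*`) + config$background_counts
      vals <- if (config$shot_noise) {
        rpois(length(lam), lam)
      } else {
        as.integer(round(lam))
      }
      vals[vals > 65535L] <- 65535L
      out[, , idx] <- vals
    }
  })
  vi_movie(out,
    frame_rate = config$frame_rate,
    exposure_ms = 2.2, origin = "simulated"
  )
}

#' Simulate a voltage-imaging movie with full ground truth
#'
#' Runs the whole generator: soma placement, per-neuron spike trains,
#' per-neuron AP kernel parameters, plateau depolarizations, dF/F0 traces,
#' and camera sampling with shot noise. All randomness derives from
#' `config$seed` through fixed sub-streams (one per neuron), so the result
#' is bit-identical for a given config and adding a neuron does not perturb
#' the others.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @return list of class `vi_sim` with elements `movie` ([vi_movie()]) and
#'   `truth` (footprints, masks, per-neuron spike tibble `spikes`,
#'   `plateaus`, per-neuron `kernels`, the generating `dff` matrix, and the
#'   config).
#' @examples
#' sim <- simulate_movie(sim_config(
#'   n_neurons = 1, fov_shape = c(24, 24),
#'   duration_s = 4, soma_radius_px = 3, seed = 2
#' ))
#' dim(sim$movie)
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "vi_sim_config"))
  n <- config$n_neurons
  fp <- make_footprints(
    n, config$fov_shape, config$overlap_fraction,
    config$soma_radius_px,
    seed = config$seed
  )
  rates <- if (is.function(config$firing_rate)) {
    config$firing_rate(n, substream_seed(config$seed, 800))
  } else {
    rep(config$firing_rate, length.out = n)
  }
  fwhms <- if (is.function(config$ap_fwhm_ms)) {
    config$ap_fwhm_ms(n, substream_seed(config$seed, 801))
  } else {
    rep(config$ap_fwhm_ms, length.out = n)
  }
  shared_onsets <- if (config$firing_pattern == "synchronized_bursting") {
    with_seed(
      substream_seed(config$seed, 802),
      poisson_times(config$burst_rate_per_min / 60, config$duration_s)
    )
  } else {
    NULL
  }
  n_t <- round(config$duration_s * config$frame_rate)
  times <- (seq_len(n_t) - 1) / config$frame_rate
  spike_list <- vector("list", n)
  plateau_list <- vector("list", n)
  D <- matrix(0, n, n_t)
  for (i in seq_len(n)) {
    st <- simulate_spike_train(
      rates[i], config$firing_pattern, config$duration_s,
      refractory_ms = config$refractory_ms,
      seed = substream_seed(config$seed, i),
      burst_rate_per_min = config$burst_rate_per_min,
      burst_onsets = shared_onsets
    )
    pl <- simulate_plateaus(
      config$plateau_rate_per_min, config$duration_s,
      config$plateau_duration_s, substream_seed(config$seed, 400 + i)
    )
    spike_list[[i]] <- tibble(neuron_id = i, time_s = st)
    plateau_list[[i]] <- dplyr::mutate(pl, neuron_id = i, .before = 1)
    D[i, ] <- truth_dff_trace(
      times, st, fwhms[i], config$ap_amplitude_pct, config$ap_shape,
      pl, config$plateau_amplitude_pct
    )
  }
  truth <- list(
    footprints = fp$footprints, masks = fp$masks, centers = fp$centers,
    spikes = dplyr::bind_rows(spike_list),
    plateaus = dplyr::bind_rows(plateau_list),
    kernels = tibble(
      neuron_id = seq_len(n), fwhm_ms = fwhms,
      amplitude_pct = config$ap_amplitude_pct, firing_rate_hz = rates
    ),
    dff = D, config = config
  )
  movie <- render_movie(truth, config)
  structure(list(movie = movie, truth = truth), class = "vi_sim")
}

#' Persist a simulation to disk
#'
#' Writes the movie as multi-page 16-bit TIFF (+ JSON sidecar), the
#' footprints as a TIFF stack, spike times as CSV
#' (`neuron_id, time_s`) and the remaining ground truth (kernel parameters,
#' plateau intervals, config scalars) as JSON.
#'
#' @param sim a `vi_sim` from [simulate_movie()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_movie(sim$movie, file.path(dir, "movie.tif"))
  fp <- sim$truth$footprints
  fp_pages <- lapply(
    seq_len(dim(fp)[3]),
    function(i) fp[, , i] / max(fp[, , i])
  )
  tiff::writeTIFF(fp_pages, file.path(dir, "footprints.tif"),
    bits.per.sample = 16L
  )
  write.csv(sim$truth$spikes, file.path(dir, "spikes.csv"),
    row.names = FALSE
  )
  cfg <- sim$truth$config
  cfg_json <- cfg[!vapply(cfg, is.function, TRUE)]
  jsonlite::write_json(
    list(
      config = cfg_json, kernels = sim$truth$kernels,
      plateaus = sim$truth$plateaus
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
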