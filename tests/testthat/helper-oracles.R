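# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / exhaustive enumeration, not the
# vectorised production code paths.

# Direct evaluation of the nonlinear energy operator, sample by sample.
oracle_neo <- function(s) {
  out <- numeric(length(s) - 2)
  for (t in 2:(length(s) - 1)) {
    out[t - 1] <- s[t]^2 - s[t - 1] * s[t + 1]
  }
  out
}

# Exhaustive burst finder: enumerate every contiguous window, keep those
# with >= min_spikes spikes and mean ISI below the bound, then select
# disjoint windows left to right, earliest start first, longest window on
# ties of start.
oracle_bursts <- function(times, max_mean_isi_s = 0.25, min_spikes = 4) {
  times <- sort(times)
  n <- length(times)
  qual <- list()
  if (n >= min_spikes) {
    for (i in 1:(n - min_spikes + 1)) {
      for (j in (i + min_spikes - 1):n) {
        if ((times[j] - times[i]) / (j - i) < max_mean_isi_s) {
          qual[[length(qual) + 1]] <- c(i, j)
        }
      }
    }
  }
  sel <- list()
  pos <- 1
  while (TRUE) {
    cand <- Filter(function(w) w[1] >= pos, qual)
    if (!length(cand)) break
    starts <- vapply(cand, `[`, 0, 1)
    cand <- cand[starts == min(starts)]
    ends <- vapply(cand, `[`, 0, 2)
    w <- cand[[which.max(ends)]]
    sel[[length(sel) + 1]] <- w
    pos <- w[2] + 1
  }
  sel
}

# Maximum-score-first refractory resolution by explicit repeated global
# argmax (rather than a pre-sorted scan).
oracle_min_isi <- function(times_ms, scores, min_isi_ms) {
  kept <- numeric(0)
  avail <- rep(TRUE, length(times_ms))
  while (any(avail)) {
    i <- which(avail)[which.max(scores[avail])]
    if (!length(kept) || all(abs(kept - times_ms[i]) >= min_isi_ms)) {
      kept <- c(kept, times_ms[i])
    }
    avail[i] <- FALSE
  }
  sort(kept)
}

# Small helper: tibble trace from a dff vector at a frame rate.
trace_tbl <- function(dff, frame_rate = 500, neuron_id = 1L) {
  tibble::tibble(
    neuron_id = neuron_id,
    time_s = (seq_along(dff) - 1) / frame_rate,
    dff = dff
  )
}

# A small, quick simulated recording shared by several tests.
small_sim_config <- function(seed = 7, ...) {
  sim_config(
    n_neurons = 3, fov_shape = c(32, 40), duration_s = 20,
    firing_rate = 2, soma_radius_px = 3, plateau_rate_per_min = 0,
    seed = seed, ...
  )
}
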