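# Plateau depolarizations, burst detection, event taxonomy, firing stats.

#' Detect plateau depolarizations in a dF/F0 trace
#'
#' Slow sustained elevations are found on a spike-free version of the
#' trace: a running-median prefilter (window ~80 ms) removes brief APs, a
#' zero-phase low-pass (Butterworth order 2, `lowpass_cutoff_hz`) isolates
#' the slow envelope, and a plateau is any maximal interval where the slow
#' signal exceeds `k_sd` times a robust (median absolute deviation) noise
#' floor for at least `min_duration_ms`.
#'
#' @param data tibble with `time_s`, `dff` (optionally `neuron_id`).
#' @param lowpass_cutoff_hz low-pass corner, well below the AP band
#'   (default 5 Hz).
#' @param k_sd threshold in noise-floor SDs (default 3).
#' @param min_duration_ms minimum plateau duration (default 200 ms).
#' @return tibble `neuron_id`, `start_s`, `end_s` (non-overlapping).
#' @export
detect_plateaus <- function(data, lowpass_cutoff_hz = 5, k_sd = 3,
                            min_duration_ms = 200) {
  dplyr::bind_rows(lapply(split_by_neuron(data), function(df) {
    fr <- frame_rate_of(df)
    s <- df$dff
    med_win <- max(3L, round(0.08 * fr))
    if (med_win %% 2 == 0) med_win <- med_win + 1L
    despiked <- stats::runmed(s, med_win)
    bf <- signal::butter(2, min(lowpass_cutoff_hz / (fr / 2), 0.99))
    slow <- signal::filtfilt(bf, despiked)
    floor_sd <- stats::mad(slow, center = 0)
    if (floor_sd == 0) floor_sd <- stats::mad(slow)
    above <- slow > k_sd * floor_sd
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths >= min_duration_ms / 1000 * fr)
    if (!any(keep)) {
      return(tibble(
        neuron_id = df$neuron_id[1][0], start_s = numeric(0),
        end_s = numeric(0)
      ))
    }
    tibble(
      neuron_id = df$neuron_id[1],
      start_s = df$time_s[starts[keep]],
      end_s = df$time_s[ends[keep]]
    )
  }))
}

#' Detect bursts in a spike train
#'
#' A burst is any sequence of four or more APs whose mean inter-spike
#' interval is shorter than `max_mean_isi_ms` (250 ms). Scanning left to
#' right, the detector emits the longest qualifying window at the earliest
#' possible start, then continues after it, so reported bursts are disjoint
#' and each satisfies the defining predicate.
#'
#' @param spikes spike tibble (or any tibble with `neuron_id`,
#'   `time_s`), times sorted within neuron.
#' @param max_mean_isi_ms burst criterion on the mean ISI (default 250 ms).
#' @param min_spikes minimum spikes per burst (default 4).
#' @return tibble `neuron_id`, `burst_id`, `start_s`, `end_s`, `n_spikes`,
#'   `mean_isi_s`, `duration_s`, plus `first_index`/`last_index` into the
#'   neuron's spike train.
#' @examples
#' sp <- tibble::tibble(neuron_id = 1L, time_s = c(0, 0.1, 0.2, 0.3))
#' detect_bursts(sp)$n_spikes # 4
#' @export
detect_bursts <- function(spikes, max_mean_isi_ms = 250, min_spikes = 4L) {
  out <- dplyr::bind_rows(lapply(split_by_neuron(spikes), function(df) {
    times <- sort(df$time_s)
    n <- length(times)
    res <- list()
    i <- 1L
    while (i + min_spikes - 1L <= n) {
      j <- longest_burst_window(times, i, max_mean_isi_ms / 1000, min_spikes)
      if (is.na(j)) {
        i <- i + 1L
        next
      }
      res[[length(res) + 1L]] <- tibble(
        neuron_id = df$neuron_id[1],
        start_s = times[i], end_s = times[j],
        n_spikes = j - i + 1L,
        mean_isi_s = (times[j] - times[i]) / (j - i),
        duration_s = times[j] - times[i],
        first_index = i, last_index = j
      )
      i <- j + 1L
    }
    dplyr::bind_rows(res)
  }))
  if (!nrow(out)) {
    return(tibble(
      neuron_id = integer(0), burst_id = integer(0), start_s = numeric(0),
      end_s = numeric(0), n_spikes = integer(0), mean_isi_s = numeric(0),
      duration_s = numeric(0), first_index = integer(0),
      last_index = integer(0)
    ))
  }
  out <- dplyr::group_by(out, .data$neuron_id)
  out <- dplyr::mutate(out, burst_id = dplyr::row_number(), .after = 1)
  dplyr::ungroup(out)
}

# Longest qualifying window starting at spike index i, or NA. A window
# [i..j] qualifies when it holds >= min_spikes spikes and its mean ISI
# (t_j - t_i)/(j - i) is below the bound. All end points are checked: a
# longer window can qualify even when a shorter one does not, because the
# mean ISI falls again as dense spikes accrue.
longest_burst_window <- function(times, i, max_mean_isi_s, min_spikes = 4L) {
  n <- length(times)
  jmin <- i + min_spikes - 1L
  if (jmin > n) {
    return(NA_integer_)
  }
  js <- jmin:n
  ok <- (times[js] - times[i]) / (js - i) < max_mean_isi_s
  if (!any(ok)) {
    return(NA_integer_)
  }
  js[max(which(ok))]
}

#' Classify spikes into singlets, doublets, triplets and bursts
#'
#' Spikes not absorbed into bursts are grouped by gap clustering (successive
#' spikes closer than the burst ISI bound join one group); groups of one,
#' two or three spikes become singlet, doublet or triplet events. Each event
#' is tagged `on_plateau` when its median spike time falls inside a detected
#' plateau interval. Together with bursts this yields a complete partition
#' of the spike train.
#'
#' @param spikes spike tibble (`neuron_id`, `time_s`).
#' @param bursts output of [detect_bursts()] on the same spikes.
#' @param plateaus output of [detect_plateaus()] (may be empty).
#' @param gap_ms clustering gap, defaulting to the burst ISI bound (250 ms).
#' @return tibble `neuron_id`, `event_id`, `type` (factor singlet/doublet/
#'   triplet/burst), `n_spikes`, `start_s`, `end_s`, `on_plateau`.
#' @export
classify_events <- function(spikes, bursts, plateaus = NULL, gap_ms = 250) {
  plateaus <- plateaus %||% tibble(
    neuron_id = integer(0),
    start_s = numeric(0), end_s = numeric(0)
  )
  burst_split <- if (nrow(bursts)) split(bursts, bursts$neuron_id) else list()
  out <- dplyr::bind_rows(lapply(split_by_neuron(spikes), function(df) {
    id <- df$neuron_id[1]
    times <- sort(df$time_s)
    b <- burst_split[[as.character(id)]]
    in_burst <- rep(FALSE, length(times))
    ev <- list()
    if (!is.null(b)) {
      for (k in seq_len(nrow(b))) {
        idx <- b$first_index[k]:b$last_index[k]
        if (any(in_burst[idx])) {
          abort("inconsistent burst input: spike assigned twice")
        }
        in_burst[idx] <- TRUE
        ev[[length(ev) + 1L]] <- tibble(
          neuron_id = id, type = "burst", n_spikes = length(idx),
          start_s = times[idx[1]], end_s = times[idx[length(idx)]],
          median_s = median(times[idx])
        )
      }
    }
    free <- times[!in_burst]
    if (length(free)) {
      grp <- cumsum(c(1, diff(free) >= gap_ms / 1000))
      for (g in unique(grp)) {
        tt <- free[grp == g]
        type <- c("singlet", "doublet", "triplet")[min(length(tt), 3)]
        if (length(tt) >= 4) type <- "burst" # by construction; defensive
        ev[[length(ev) + 1L]] <- tibble(
          neuron_id = id, type = type, n_spikes = length(tt),
          start_s = tt[1], end_s = tt[length(tt)], median_s = median(tt)
        )
      }
    }
    dplyr::bind_rows(ev)
  }))
  if (!nrow(out)) {
    return(tibble(
      neuron_id = integer(0), event_id = integer(0), type = character(0),
      n_spikes = integer(0), start_s = numeric(0), end_s = numeric(0),
      on_plateau = logical(0)
    ))
  }
  out <- dplyr::arrange(out, .data$neuron_id, .data$start_s)
  pl_split <- if (nrow(plateaus)) split(plateaus, plateaus$neuron_id) else list()
  out$on_plateau <- vapply(seq_len(nrow(out)), function(i) {
    pl <- pl_split[[as.character(out$neuron_id[i])]]
    if (is.null(pl) || !nrow(pl)) {
      return(FALSE)
    }
    any(out$median_s[i] >= pl$start_s & out$median_s[i] <= pl$end_s)
  }, logical(1))
  out$median_s <- NULL
  out <- dplyr::group_by(out, .data$neuron_id)
  out <- dplyr::mutate(out, event_id = dplyr::row_number(), .after = 1)
  dplyr::ungroup(out)
}

#' Per-neuron firing statistics
#'
#' Instantaneous firing rate is operationalised as spike count divided by
#' recording duration (Hz); bursting rate as bursts per minute. Inter-spike
#' intervals, inter-burst intervals (onset to onset) and burst durations
#' (first to last spike) are summarised by their means; the full lists are
#' attached as list-columns.
#'
#' @param spikes spike tibble (`neuron_id`, `time_s`).
#' @param bursts [detect_bursts()] output.
#' @param duration_s recording duration (`> 0`).
#' @param neuron_ids optional vector of neurons to report (so silent
#'   neurons appear with zero rates).
#' @return one row per neuron: `neuron_id`, `n_spikes`, `firing_rate_hz`,
#'   `n_bursts`, `bursting_rate_per_min`, `mean_isi_s`, `mean_ibi_s`,
#'   `mean_burst_duration_s`, `isi` / `ibi` / `burst_durations`
#'   list-columns, `duration_s`.
#' @examples
#' sp <- tibble::tibble(neuron_id = 1L, time_s = seq(0.5, 180, 1))
#' compute_firing_stats(sp, detect_bursts(sp), 180)$firing_rate_hz # 1
#' @export
compute_firing_stats <- function(spikes, bursts, duration_s,
                                 neuron_ids = NULL) {
  if (duration_s <= 0) abort("`duration_s` must be positive")
  ids <- neuron_ids %||% sort(unique(spikes$neuron_id))
  rows <- lapply(ids, function(id) {
    tt <- sort(spikes$time_s[spikes$neuron_id == id])
    b <- bursts[bursts$neuron_id == id, , drop = FALSE]
    isi <- diff(tt)
    ibi <- if (nrow(b) >= 2) diff(b$start_s) else numeric(0)
    bd <- b$duration_s
    tibble(
      neuron_id = id, n_spikes = length(tt),
      firing_rate_hz = length(tt) / duration_s,
      n_bursts = nrow(b),
      bursting_rate_per_min = nrow(b) / duration_s * 60,
      mean_isi_s = if (length(isi)) mean(isi) else NA_real_,
      mean_ibi_s = if (length(ibi)) mean(ibi) else NA_real_,
      mean_burst_duration_s = if (length(bd)) mean(bd) else NA_real_,
      isi = list(isi), ibi = list(ibi), burst_durations = list(bd),
      duration_s = duration_s
    )
  })
  dplyr::bind_rows(rows)
}
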