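# Action-potential detection with the nonlinear energy operator (NEO).

#' Nonlinear energy operator of a dF/F0 trace
#'
#' Computes `psi(t) = s(t)^2 - s(t-1) * s(t+1)` on the interior samples of
#' each neuron's trace (the first and last frame carry no value). The
#' operator emphasises brief high-frequency transients such as action
#' potentials while staying near zero for slow signal and baseline noise.
#' This is an exact arithmetic contract: no smoothing happens inside.
#'
#' @param data tibble with `time_s` and `dff` (optionally `neuron_id`).
#' @return tibble `neuron_id`, `time_s`, `frame` (index into the input
#'   trace), `neo` in (percent dF/F0)^2 units.
#' @examples
#' tr <- tibble::tibble(time_s = (0:4) / 500, dff = c(0, 0, 1, 0, 0))
#' neo_transform(tr)$neo # 0 1 0
#' @export
neo_transform <- function(data) {
  stopifnot(is.data.frame(data), all(c("time_s", "dff") %in% names(data)))
  dplyr::bind_rows(lapply(split_by_neuron(data), function(df) {
    s <- df$dff
    n <- length(s)
    if (n < 3) abort("NEO needs at least 3 samples")
    core <- 2:(n - 1)
    tibble(
      neuron_id = df$neuron_id[1],
      time_s = df$time_s[core],
      frame = core,
      neo = s[core]^2 - s[core - 1] * s[core + 1]
    )
  }))
}

# Leftmost local maxima: strictly above the left neighbour, at least the
# right one (plateaus contribute their first sample only).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(integer(0))
  }
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Find candidate spikes in a NEO signal
#'
#' Local maxima of the NEO signal at or above `k_sd` standard deviations of
#' the NEO signal (SD taken over the full epoch, about zero mean) become
#' candidates; each candidate's spike frame is the dF/F0 local maximum
#' within two frames of the NEO peak. A constant trace (SD zero) yields no
#' candidates.
#'
#' @param neo output of [neo_transform()].
#' @param data the matching dF/F0 tibble (for peak relocation).
#' @param k_sd threshold in NEO standard deviations (default 3).
#' @return tibble `neuron_id`, `frame`, `time_s`, `neo_score`, `threshold`.
#' @export
detect_peaks <- function(neo, data, k_sd = 3) {
  if (k_sd <= 0) abort("`k_sd` must be positive")
  neo_split <- split_by_neuron(neo)
  data_split <- split_by_neuron(data)
  dplyr::bind_rows(lapply(names(neo_split), function(id) {
    nd <- neo_split[[id]]
    df <- data_split[[id]]
    psi <- nd$neo
    # SD about zero: psi of noise is near-zero-mean by construction
    thr <- k_sd * sqrt(mean(psi^2))
    if (thr == 0) {
      return(tibble(
        neuron_id = integer(0), frame = integer(0),
        time_s = numeric(0), neo_score = numeric(0), threshold = numeric(0)
      ))
    }
    peaks <- local_maxima(psi)
    peaks <- peaks[psi[peaks] >= thr]
    if (!length(peaks)) {
      return(tibble(
        neuron_id = integer(0), frame = integer(0),
        time_s = numeric(0), neo_score = numeric(0), threshold = numeric(0)
      ))
    }
    s <- df$dff
    frames <- vapply(peaks, function(p) {
      # nd$frame maps NEO sample -> trace sample
      ctr <- nd$frame[p]
      win <- max(1L, ctr - 2L):min(length(s), ctr + 2L)
      win[which.max(s[win])]
    }, integer(1))
    out <- tibble(
      neuron_id = df$neuron_id[1], frame = frames,
      time_s = df$time_s[frames], neo_score = psi[peaks], threshold = thr
    )
    # two NEO peaks may relocate to one dF/F0 maximum: keep the higher score
    out <- out[order(-out$neo_score), ]
    out <- out[!duplicated(out$frame), ]
    out[order(out$frame), ]
  }))
}

#' Enforce a minimum inter-spike interval
#'
#' Candidates are scanned in descending NEO score; one is kept iff no
#' already-kept spike of the same neuron lies within `min_isi_ms`. This
#' removes double counts when one AP crosses threshold twice on noisy
#' recordings, deterministically favouring the stronger detection.
#'
#' @param candidates tibble from [detect_peaks()].
#' @param min_isi_ms hard inter-spike-interval limit (default 20 ms).
#' @return spike tibble `neuron_id`, `frame`, `time_s`, `neo_score`,
#'   `threshold`, sorted by time within neuron.
#' @export
enforce_min_isi <- function(candidates, min_isi_ms = 20) {
  if (min_isi_ms < 0) abort("`min_isi_ms` must be nonnegative")
  out <- dplyr::bind_rows(lapply(split_by_neuron(candidates), function(df) {
    df <- df[order(-df$neo_score, df$time_s), ]
    kept_times <- numeric(0)
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!length(kept_times) ||
        all(abs(kept_times - df$time_s[i]) >= min_isi_ms / 1000)) {
        keep[i] <- TRUE
        kept_times <- c(kept_times, df$time_s[i])
      }
    }
    df[keep, ][order(df$time_s[keep]), ]
  }))
  as_tibble(out)
}

#' Detect action potentials in dF/F0 traces
#'
#' Full detector: [neo_transform()], [detect_peaks()] at `k_sd` standard
#' deviations, then [enforce_min_isi()]. Because the threshold is relative
#' to the NEO SD, detection is invariant to rescaling the trace.
#'
#' @param data tibble with `time_s`, `dff` and optionally `neuron_id`.
#' @param k_sd NEO threshold in SD units (default 3).
#' @param min_isi_ms hard minimum inter-spike interval (default 20 ms).
#' @param smooth_window optional odd moving-average window (frames) applied
#'   to the trace before NEO; `1` leaves the trace untouched.
#' @param highpass_ms width of a running-median slow envelope subtracted
#'   from the trace before NEO (`0` disables). NEO is not offset-invariant:
#'   a sustained plateau depolarization of amplitude `b` adds
#'   `b * (2 s(t) - s(t-1) - s(t+1))` of amplified noise to the NEO signal,
#'   which produces spurious detections on plateaus. A running median much
#'   wider than an AP removes the offset without touching spike amplitude.
#' @return spike tibble (see [enforce_min_isi()]).
#' @examples
#' tr <- tibble::tibble(
#'   time_s = (0:199) / 500,
#'   dff = replace(rnorm(200, 0, 0.1), 100, 8)
#' )
#' detect_spikes(tr)$frame # 100
#' @export
detect_spikes <- function(data, k_sd = 3, min_isi_ms = 20,
                          smooth_window = 1L, highpass_ms = 80) {
  if (smooth_window > 1L || highpass_ms > 0) {
    fr <- frame_rate_of(data)
    data <- dplyr::bind_rows(lapply(split_by_neuron(data), function(df) {
      if (highpass_ms > 0) {
        k <- max(3L, round(highpass_ms / 1000 * fr))
        if (k %% 2L == 0L) k <- k + 1L
        if (k < length(df$dff)) {
          df$dff <- df$dff - stats::runmed(df$dff, k)
        }
      }
      if (smooth_window > 1L) {
        df$dff <- moving_average(df$dff, smooth_window)
      }
      df
    }))
  }
  neo <- neo_transform(data)
  cand <- detect_peaks(neo, data, k_sd = k_sd)
  enforce_min_isi(cand, min_isi_ms = min_isi_ms)
}
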