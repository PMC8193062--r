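# Ground-truth spike trains.

# Homogeneous Poisson process on [0, duration) by exponential gaps.
poisson_times <- function(rate, duration_s) {
  if (rate <= 0) {
    return(numeric(0))
  }
  times <- numeric(0)
  t <- rexp(1, rate)
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + rexp(1, rate)
  }
  times
}

thin_refractory <- function(times, refractory_s) {
  if (length(times) < 2 || refractory_s <= 0) {
    return(times)
  }
  keep <- times[1]
  last <- times[1]
  for (t in times[-1]) {
    if (t - last >= refractory_s) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

burst_cluster <- function(onset) {
  n <- sample(4:8, 1)
  onset + cumsum(c(0, runif(n - 1, 0.05, 0.2)))
}

#' Simulate a ground-truth spike train
#'
#' @param firing_rate mean rate in Hz. For the bursting patterns this is the
#'   rate of isolated (non-burst) spikes; bursts are added on top at
#'   `burst_rate_per_min`.
#' @param pattern `"poisson"` (homogeneous Poisson thinned by an absolute
#'   refractory period), `"bursting"` (Poisson burst onsets, each emitting
#'   4-8 spikes at intra-burst intervals of 50-200 ms, plus isolated spikes)
#'   or `"synchronized_bursting"` (burst onsets supplied externally via
#'   `burst_onsets`, jittered per neuron, emulating network bursts).
#' @param duration_s epoch length in seconds.
#' @param refractory_ms absolute refractory period.
#' @param seed RNG seed for this train.
#' @param burst_rate_per_min burst-onset rate (bursting patterns).
#' @param burst_onsets shared network-burst onset times
#'   (`synchronized_bursting` only).
#' @param participation probability that this neuron joins a network burst.
#' @return strictly increasing spike times (seconds) in `[0, duration_s)`.
#' @examples
#' simulate_spike_train(0, "poisson", 180, seed = 1) # empty
#' @export
simulate_spike_train <- function(firing_rate,
                                 pattern = c(
                                   "poisson", "bursting",
                                   "synchronized_bursting"
                                 ),
                                 duration_s, refractory_ms = 5, seed = 1L,
                                 burst_rate_per_min = 6,
                                 burst_onsets = NULL,
                                 participation = 0.8) {
  pattern <- match.arg(pattern)
  if (firing_rate < 0) abort("`firing_rate` must be nonnegative")
  if (refractory_ms < 0) abort("`refractory_ms` must be nonnegative")
  with_seed(seed, {
    times <- switch(pattern,
      poisson = poisson_times(firing_rate, duration_s),
      bursting = {
        onsets <- poisson_times(burst_rate_per_min / 60, duration_s)
        c(
          unlist(lapply(onsets, burst_cluster)),
          poisson_times(firing_rate, duration_s)
        )
      },
      synchronized_bursting = {
        onsets <- burst_onsets %||%
          poisson_times(burst_rate_per_min / 60, duration_s)
        joined <- onsets[runif(length(onsets)) < participation]
        joined <- joined + rnorm(length(joined), 0, 0.02)
        c(
          unlist(lapply(joined, burst_cluster)),
          poisson_times(firing_rate, duration_s)
        )
      }
    )
    times <- sort(times[times >= 0 & times < duration_s])
    thin_refractory(times, refractory_ms / 1000)
  })
}
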