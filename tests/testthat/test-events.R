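spikes_tbl <- function(times, id = 1L) {
  tibble::tibble(neuron_id = id, time_s = times)
}

test_that("burst definition: four spikes at 100 ms ISIs, but not three", {
  b <- detect_bursts(spikes_tbl(c(0, 0.1, 0.2, 0.3)))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 4L)
  expect_equal(b$mean_isi_s, 0.1)
  expect_equal(detect_bursts(spikes_tbl(c(0, 0.1, 0.2)))$n_spikes, integer(0))
})

test_that("burst detection matches exhaustive enumeration on random trains", {
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(0:15, 1)
    times <- sort(runif(n, 0, 3))
    b <- detect_bursts(spikes_tbl(times))
    oracle <- oracle_bursts(times)
    expect_equal(nrow(b), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_equal(b$first_index, om[, 1])
      expect_equal(b$last_index, om[, 2])
    }
  }
})

test_that("every reported burst satisfies its defining predicate", {
  set.seed(21)
  for (i in 1:50) {
    times <- sort(c(runif(30, 0, 60), 10 + cumsum(runif(8, 0.02, 0.2))))
    b <- detect_bursts(spikes_tbl(times))
    for (k in seq_len(nrow(b))) {
      run <- times[times >= b$start_s[k] & times <= b$end_s[k]]
      expect_gte(length(run), 4)
      expect_lt(mean(diff(run)), 0.25)
    }
  }
})

test_that("burst detection is invariant to the time origin", {
  times <- c(0.5, 0.6, 0.7, 0.8, 5, 9, 9.05, 9.1, 9.15, 9.2)
  a <- detect_bursts(spikes_tbl(times))
  b <- detect_bursts(spikes_tbl(times + 123.4))
  expect_equal(a$n_spikes, b$n_spikes)
  expect_equal(b$start_s - a$start_s, rep(123.4, nrow(a)))
})

test_that("flat traces with spikes only yield no plateaus", {
  set.seed(22)
  s <- rnorm(20000, 0, 0.2)
  s[seq(500, 19500, by = 500)] <- 12
  expect_equal(nrow(detect_plateaus(trace_tbl(s))), 0)
})

test_that("a rendered 1 s plateau is found with good overlap", {
  set.seed(23)
  t <- (0:29999) / 500
  slow <- voltrace:::plateau_waveform(t, 30, 31, 3)
  s <- slow + rnorm(length(t), 0, 0.3)
  pl <- detect_plateaus(trace_tbl(s))
  expect_equal(nrow(pl), 1)
  jac <- (min(pl$end_s, 31) - max(pl$start_s, 30)) /
    (max(pl$end_s, 31) - min(pl$start_s, 30))
  expect_gt(jac, 0.7)
})

test_that("two separated plateaus give two intervals", {
  t <- (0:29999) / 500
  slow <- voltrace:::plateau_waveform(t, 10, 11, 3) +
    voltrace:::plateau_waveform(t, 13, 14.5, 3)
  set.seed(24)
  s <- slow + rnorm(length(t), 0, 0.25)
  pl <- detect_plateaus(trace_tbl(s))
  expect_equal(nrow(pl), 2)
})

test_that("events partition the spike train", {
  set.seed(25)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    times <- sort(runif(n, 0, 4))
    sp <- spikes_tbl(times)
    b <- detect_bursts(sp)
    ev <- classify_events(sp, b)
    expect_equal(sum(ev$n_spikes), n)
    n_singlet <- sum(ev$type == "singlet")
    n_doublet <- sum(ev$type == "doublet")
    n_triplet <- sum(ev$type == "triplet")
    n_burst_spikes <- sum(ev$n_spikes[ev$type == "burst"])
    expect_equal(n_singlet + 2 * n_doublet + 3 * n_triplet + n_burst_spikes, n)
  }
})

test_that("event taxonomy and plateau tagging follow the definitions", {
  sp <- spikes_tbl(c(1, 5, 5.1, 9, 9.1, 9.2))
  pl <- tibble::tibble(neuron_id = 1L, start_s = 4.5, end_s = 5.5)
  ev <- classify_events(sp, detect_bursts(sp), pl)
  expect_equal(ev$type, c("singlet", "doublet", "triplet"))
  expect_equal(ev$on_plateau, c(FALSE, TRUE, FALSE))
})

test_that("firing statistics arithmetic", {
  sp <- spikes_tbl(seq(0.5, 179.5, 1)) # 180 spikes in 180 s
  st <- compute_firing_stats(sp, detect_bursts(sp), 180)
  expect_equal(st$firing_rate_hz, 1)
  expect_equal(st$n_bursts, 0L)

  empty <- compute_firing_stats(
    spikes_tbl(numeric(0)), detect_bursts(spikes_tbl(numeric(0))),
    180,
    neuron_ids = 1L
  )
  expect_equal(empty$firing_rate_hz, 0)
  expect_equal(empty$n_spikes, 0L)
  expect_length(empty$isi[[1]], 0)

  expect_error(compute_firing_stats(sp, detect_bursts(sp), 0), "positive")
})

test_that("burst statistics: IBI onset-to-onset, duration first-to-last", {
  times <- c(
    10 + c(0, 0.1, 0.2, 0.3),
    40 + c(0, 0.05, 0.1, 0.15, 0.2)
  )
  sp <- spikes_tbl(times)
  b <- detect_bursts(sp)
  st <- compute_firing_stats(sp, b, 60)
  expect_equal(st$n_bursts, 2L)
  expect_equal(st$bursting_rate_per_min, 2)
  expect_equal(st$ibi[[1]], 30)
  expect_equal(st$burst_durations[[1]], c(0.3, 0.2))
})

test_that("rate additivity for disjoint-in-time merged trains", {
  a <- seq(0.2, 50, 1)
  b <- seq(60, 110, 0.5)
  ra <- compute_firing_stats(spikes_tbl(a), detect_bursts(spikes_tbl(a)), 120)
  rb <- compute_firing_stats(spikes_tbl(b), detect_bursts(spikes_tbl(b)), 120)
  rc <- compute_firing_stats(
    spikes_tbl(sort(c(a, b))),
    detect_bursts(spikes_tbl(sort(c(a, b)))), 120
  )
  expect_equal(
    rc$firing_rate_hz,
    ra$firing_rate_hz + rb$firing_rate_hz
  )
})
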