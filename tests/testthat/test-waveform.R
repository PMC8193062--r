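gauss_segment <- function(sigma_ms = 5, amp = 10, frame_rate = 500,
                          base = 0, window_ms = 300) {
  half <- round(window_ms * frame_rate / 2000)
  t <- (-half:half) * 1000 / frame_rate
  base + amp * exp(-t^2 / (2 * sigma_ms^2))
}

test_that("segment geometry follows the window arithmetic", {
  s <- c(rep(0, 1000), 10, rep(0, 1000))
  tr <- trace_tbl(pmax(s, 0.001))
  sp <- detect_spikes(tr, highpass_ms = 0)
  wf <- extract_waveforms(tr, sp, window_ms = 300)
  expect_equal(ncol(wf$segments), 151) # round(300*500/1000)+1
  expect_equal(wf$peak_index, 76)
})

test_that("edge spikes are excluded and counted", {
  s <- rep(0.001, 90000)
  s[c(25, 45000, 89990)] <- 10 # 50 ms, mid, near end of a 180 s trace
  tr <- trace_tbl(s)
  sp <- detect_spikes(tr, highpass_ms = 0)
  expect_equal(nrow(sp), 3)
  wf <- extract_waveforms(tr, sp, window_ms = 300)
  expect_equal(nrow(wf$segments), 1)
  expect_equal(wf$n_edge_excluded, 2)
})

test_that("Gaussian pulse FWHM matches 2*sqrt(2 ln 2)*sigma", {
  expect_equal(compute_fwhm(gauss_segment(5), 500), 11.774, tolerance = 0.01)
  # invariant to offsets and positive scaling
  expect_equal(compute_fwhm(gauss_segment(5, base = 7), 500),
    compute_fwhm(gauss_segment(5), 500),
    tolerance = 1e-9
  )
  expect_equal(compute_fwhm(3 * gauss_segment(5), 500),
    compute_fwhm(gauss_segment(5), 500),
    tolerance = 1e-9
  )
})

test_that("triangular pulse of 20 ms base has 10 ms FWHM", {
  fr <- 500
  half <- 75
  t <- (-half:half) * 2 # ms
  seg <- pmax(0, 1 - abs(t) / 10) * 8
  expect_equal(compute_fwhm(seg, fr), 10, tolerance = 1e-9)
})

test_that("truncated waveforms are flagged, not guessed", {
  seg <- gauss_segment(5)
  rising_only <- seg
  rising_only[76:151] <- seg[76] # never decays
  expect_true(is.na(compute_fwhm(rising_only, 500)))
  p <- waveform_params(rep(0, 151), 500)
  expect_false(p$valid)
})

test_that("rise and decay times recover the kernel's asymmetry", {
  fr <- 2000 # dense sampling to compare against the closed form
  k <- render_ap_kernel(12, 10, fr)
  half <- 150
  seg <- numeric(2 * half + 1)
  at <- half + 1 - (attr(k, "peak_index") - 1) + seq_along(k$dff) - 1
  seg[at[at >= 1 & at <= length(seg)]] <- k$dff[at >= 1 & at <= length(seg)]
  p <- waveform_params(seg, fr)
  # two-sided Gaussian: rise 10-90% = sigma_r*(sqrt(2 ln 10)-sqrt(2 ln(10/9)))
  sr <- 0.25 * 12 / sqrt(2 * log(2))
  sf <- 0.75 * 12 / sqrt(2 * log(2))
  span <- sqrt(2 * log(10)) - sqrt(2 * log(10 / 9))
  expect_equal(p$rise_ms, sr * span, tolerance = 0.1)
  expect_equal(p$decay_ms, sf * span, tolerance = 0.1)
  expect_equal(p$amplitude, 10, tolerance = 1e-6)
})

test_that("amplitude scales linearly with the kernel amplitude", {
  a1 <- waveform_params(gauss_segment(5, amp = 5), 500)$amplitude
  a2 <- waveform_params(gauss_segment(5, amp = 15), 500)$amplitude
  expect_equal(a2 / a1, 3, tolerance = 1e-9)
})

test_that("FWHM at 300 Hz and 500 Hz sampling agree within a frame period", {
  f300 <- compute_fwhm(gauss_segment(6, frame_rate = 300), 300)
  f500 <- compute_fwhm(gauss_segment(6, frame_rate = 500), 500)
  expect_lt(abs(f300 - f500), 1000 / 300)
  expect_equal(f500, 2 * sqrt(2 * log(2)) * 6, tolerance = 0.02)
})

test_that("noiseless simulated trains give segments equal to the kernel", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(24, 24), duration_s = 20,
    firing_rate = 1, soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 0, ap_fwhm_ms = 12,
    refractory_ms = 300, seed = 23
  )
  sim <- simulate_movie(cfg)
  tr <- extract_traces(sim$movie, voltrace:::truth_roiset(sim$truth),
    weighting = "mask", baseline_method = "global_percentile"
  )
  sp <- detect_spikes(tr, highpass_ms = 0)
  wf <- extract_waveforms(tr, sp)
  met <- tidy(wf)
  ok <- met$valid & !met$overlapping
  expect_gt(sum(ok), 5)
  # every per-spike FWHM close to the kernel's 12 ms (sub-frame spike
  # phases vary, so allow one frame period)
  expect_true(all(abs(met$fwhm_ms[ok] - 12) < 2))
  expect_equal(mean(met$fwhm_ms[ok]), 12, tolerance = 0.05)
})

test_that("doublet-overlapping windows are retained but flagged", {
  s <- rep(0.001, 2000)
  s[c(1000, 1030)] <- 10 # 60 ms apart, window 300 ms
  tr <- trace_tbl(s)
  sp <- detect_spikes(tr, highpass_ms = 0)
  wf <- extract_waveforms(tr, sp)
  expect_equal(nrow(wf$segments), 2)
  expect_true(all(tidy(wf)$overlapping))
})

test_that("mean waveform is the column mean of aligned segments", {
  s <- rep(0.001, 3000)
  s[c(500, 1500, 2500)] <- 10
  tr <- trace_tbl(s)
  wf <- extract_waveforms(tr, detect_spikes(tr, highpass_ms = 0))
  mw <- mean_waveform(wf)
  expect_equal(nrow(mw), 151)
  expect_equal(mw$dff[76], 10, tolerance = 1e-9)
  expect_equal(mw$time_ms[76], 0)
})
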