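test_that("footprints are placed, compact and respect overlap settings", {
  fp1 <- make_footprints(1, c(64, 64), seed = 1, soma_radius_px = 6)
  expect_length(fp1$masks, 1)
  expect_gt(length(fp1$masks[[1]]), 0)

  fp2 <- make_footprints(2, c(64, 64),
    overlap_fraction = 0, seed = 1,
    soma_radius_px = 6
  )
  expect_length(intersect(fp2$masks[[1]], fp2$masks[[2]]), 0)

  # dense field comparable to a crowded field of view: all 12 placed
  fp12 <- make_footprints(12, c(150, 200), seed = 2, soma_radius_px = 6)
  expect_length(fp12$masks, 12)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      expect_length(intersect(fp12$masks[[i]], fp12$masks[[j]]), 0)
    }
  }
  expect_true(all(fp12$footprints >= 0))
})

test_that("forced overlap produces shared pixels", {
  fp <- make_footprints(4, c(64, 64),
    overlap_fraction = 1, seed = 3,
    soma_radius_px = 5
  )
  for (i in 1:3) {
    expect_gt(length(intersect(fp$masks[[i]], fp$masks[[i + 1]])), 0)
  }
})

test_that("impossible densities raise a density error", {
  expect_error(
    make_footprints(50, c(20, 20), seed = 1, soma_radius_px = 6),
    "density|too small"
  )
})

test_that("a neuron-free noiseless movie is constant background", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(16, 16), duration_s = 2,
    firing_rate = 0, plateau_rate_per_min = 0, shot_noise = FALSE,
    soma_radius_px = 3, baseline_counts = 0, background_counts = 300,
    seed = 1
  )
  sim <- simulate_movie(cfg)
  expect_true(all(sim$movie == 300))
})

test_that("noiseless render/extract round trip conserves dF/F0", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(24, 24), duration_s = 8,
    firing_rate = 2, soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 0, seed = 9
  )
  sim <- simulate_movie(cfg)
  tr <- extract_traces(sim$movie, voltrace:::truth_roiset(sim$truth),
    weighting = "mask", baseline_method = "global_percentile"
  )
  expect_lt(max(abs(tr$dff - sim$truth$dff[1, ])), 0.05)
})

test_that("rendered spikes reproduce the kernel after extraction", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(24, 24), duration_s = 6,
    firing_rate = 0, soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 0, seed = 2
  )
  sim <- simulate_movie(cfg)
  # inject one spike exactly on a frame time and re-render
  sim$truth$dff[1, ] <- voltrace:::truth_dff_trace(
    (0:(6 * 500 - 1)) / 500, 3.0, 12, 10, "asymmetric"
  )
  movie <- render_movie(sim$truth, cfg)
  tr <- extract_traces(movie, voltrace:::truth_roiset(sim$truth),
    weighting = "mask", baseline_method = "global_percentile"
  )
  idx <- which.max(tr$dff)
  expect_equal(tr$time_s[idx], 3.0)
  expect_equal(max(tr$dff), 10, tolerance = 0.01)
  seg <- tr$dff[(idx - 75):(idx + 75)]
  expect_equal(compute_fwhm(seg, 500), 12, tolerance = 0.3)
})

test_that("photobleaching decays the mean intensity with the set tau", {
  cfg <- sim_config(
    n_neurons = 2, fov_shape = c(20, 20), duration_s = 60,
    firing_rate = 0, soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 0,
    bleach_tau_s = 60, seed = 4
  )
  sim <- simulate_movie(cfg)
  m <- apply(sim$movie, 3, mean)
  t <- voltrace:::movie_times(sim$movie)
  fit <- stats::nls(
    m ~ a * exp(-t / tau),
    start = list(a = m[1], tau = 30)
  )
  expect_equal(unname(coef(fit)["tau"]), 60, tolerance = 5 / 60)
})

test_that("overflowing expected counts error with advice", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(16, 16), duration_s = 2,
    firing_rate = 0, soma_radius_px = 3, baseline_counts = 70000,
    seed = 1
  )
  expect_error(simulate_movie(cfg), "baseline_counts")
})

test_that("the generator is bit-deterministic given the seed", {
  cfg <- small_sim_config(seed = 21)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movie, b$movie)
  expect_identical(a$truth$spikes, b$truth$spikes)
})

test_that("plateau intervals are rendered and non-overlapping", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(20, 20), duration_s = 60,
    firing_rate = 0, soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 4,
    plateau_amplitude_pct = 5, seed = 6
  )
  sim <- simulate_movie(cfg)
  pl <- sim$truth$plateaus
  expect_gt(nrow(pl), 0)
  if (nrow(pl) > 1) {
    expect_true(all(pl$start_s[-1] >= pl$end_s[-nrow(pl)]))
  }
  # the trace is elevated inside a plateau
  mid <- (pl$start_s[1] + pl$end_s[1]) / 2
  i <- round(mid * 500) + 1
  expect_gt(sim$truth$dff[1, i], 4)
})
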