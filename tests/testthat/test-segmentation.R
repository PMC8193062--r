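test_that("PCA isolates low-rank structure", {
  # rank-1 movie: one footprint blinking, no noise
  fp <- voltrace:::footprint_image(c(20, 20), c(10, 10), 4)
  tt <- 1 + 0.5 * sin(seq(0, 8 * pi, length.out = 200))
  frames <- array(outer(as.numeric(fp), tt) + 100, c(20, 20, 200))
  m <- vi_movie(frames, 500)
  p <- pca_reduce(m, 5)
  expect_gt(p$var_explained[1], 0.999)

  # white noise: approximately flat spectrum, no dominant component
  set.seed(6)
  wn <- vi_movie(array(rnorm(15 * 15 * 500, 100, 1), c(15, 15, 500)), 500)
  pw <- pca_reduce(wn, 100)
  ev <- pw$eigenvalues[1:100]
  expect_lt(ev[1], 5 * median(ev))
})

test_that("three independent sources need exactly three components", {
  cfg <- sim_config(
    n_neurons = 3, fov_shape = c(24, 36), duration_s = 10,
    firing_rate = 3, soma_radius_px = 3, shot_noise = FALSE,
    plateau_rate_per_min = 0, seed = 31
  )
  sim <- simulate_movie(cfg)
  p <- pca_reduce(sim$movie, 6)
  expect_gt(sum(p$var_explained[1:3]), 0.999)
})

test_that("ICA recovers well-separated neurons as a bijection", {
  cfg <- small_sim_config(seed = 7)
  sim <- simulate_movie(cfg)
  seg <- spatiotemporal_filter(voltrace:::bin_movie(sim$movie, 3), 1, 1)
  roi <- ica_unmix(pca_reduce(seg, 9), n_ics = 3, seed = 2)
  # each temporal IC matches exactly one ground-truth trace
  D <- sim$truth$dff
  nb <- ncol(roi$temporal_ics)
  Db <- sapply(1:3, function(i) {
    colMeans(matrix(D[i, 1:(3 * floor(ncol(D) / 3))], 3))
  })
  cc <- abs(cor(roi$temporal_ics, Db))
  best <- apply(cc, 2, max)
  expect_true(all(best > 0.95))
  expect_equal(sort(apply(cc, 2, which.max)), 1:3) # bijection
})

test_that("a single neuron's IC mask overlaps the true mask", {
  cfg <- sim_config(
    n_neurons = 1, fov_shape = c(40, 40), duration_s = 15,
    firing_rate = 2, soma_radius_px = 5, plateau_rate_per_min = 0,
    seed = 17
  )
  sim <- simulate_movie(cfg)
  seg <- spatiotemporal_filter(voltrace:::bin_movie(sim$movie, 3), 1, 1)
  roi <- filters_to_masks(ica_unmix(pca_reduce(seg, 4), 1, seed = 5))
  j <- match_rois(roi$masks, sim$truth$masks)$jaccard
  expect_gt(j, 0.6)
})

test_that("ICA is deterministic given its seed", {
  cfg <- small_sim_config(seed = 7)
  sim <- simulate_movie(cfg)
  seg <- spatiotemporal_filter(voltrace:::bin_movie(sim$movie, 3), 1, 1)
  p <- pca_reduce(seg, 9)
  a <- ica_unmix(p, 3, seed = 42)
  b <- ica_unmix(p, 3, seed = 42)
  expect_identical(a$spatial_filters, b$spatial_filters)
  expect_identical(a$temporal_ics, b$temporal_ics)
})

test_that("filters_to_masks thresholds, keeps one component, shrinks monotonically", {
  d <- c(21, 21)
  f1 <- as.numeric(voltrace:::footprint_image(d, c(11, 11), 6))
  roi <- structure(
    list(
      spatial_filters = cbind(f1), temporal_ics = NULL,
      skew_spatial = 1, skew_temporal = 1, masks = NULL, dim = d
    ),
    class = "vi_roiset"
  )
  sizes <- vapply(
    c(0.2, 0.5, 0.8),
    function(th) length(filters_to_masks(roi, th)$masks[[1]]), 0
  )
  expect_true(all(diff(sizes) < 0))

  # two-lobed spurious filter: larger lobe wins
  f2 <- as.numeric(
    voltrace:::footprint_image(d, c(6, 6), 4) +
      0.9 * voltrace:::footprint_image(d, c(16, 16), 2)
  )
  roi$spatial_filters <- cbind(f2)
  mk <- filters_to_masks(roi, 0.3)$masks[[1]]
  centers_px <- matrix(c(6, 6, 16, 16), 2, byrow = TRUE)
  px_rc <- cbind((mk - 1) %% d[1] + 1, (mk - 1) %/% d[1] + 1)
  d_big <- sqrt((px_rc[, 1] - 6)^2 + (px_rc[, 2] - 6)^2)
  expect_true(all(d_big <= 5)) # only the large lobe survives
  expect_error(filters_to_masks(roi, 1.2), "0, 1")
})

test_that("traces from disjoint neurons do not cross-contaminate", {
  cfg <- sim_config(
    n_neurons = 2, fov_shape = c(24, 40), duration_s = 10,
    firing_rate = c(0, 4), soma_radius_px = 3, shot_noise = FALSE,
    background_counts = 0, plateau_rate_per_min = 0, seed = 19
  )
  sim <- simulate_movie(cfg)
  tr <- extract_traces(sim$movie, voltrace:::truth_roiset(sim$truth),
    weighting = "mask", baseline_method = "global_percentile"
  )
  silent <- tr$dff[tr$neuron_id == 1]
  active <- tr$dff[tr$neuron_id == 2]
  expect_lt(max(abs(silent)), 0.05)
  expect_gt(max(active), 5)
})

test_that("masks outside the field of view are rejected", {
  m <- vi_movie(array(10, c(8, 8, 5)), 500)
  roi <- list(masks = list(c(1, 200)), spatial_filters = NULL)
  expect_error(extract_traces(m, roi, weighting = "mask"), "outside")
})
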