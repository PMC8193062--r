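# Soma footprints: smooth, compact spatial weight maps.

# Soma-like radial profile on the pixel grid: a flat-top disc with a
# raised-cosine rim (somas are filled, softly bounded discs, not Gaussian
# points). Weight is 1 inside 0.7*radius, falls to 0 at `radius`; the
# half-maximum level sits at 0.85*radius, so half-max level sets track the
# support closely.
footprint_image <- function(fov, center, radius) {
  H <- fov[1]
  W <- fov[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  core <- 0.7 * radius
  w <- matrix(0, H, W)
  w[d <= core] <- 1
  rim <- d > core & d < radius
  w[rim] <- 0.5 * (1 + cos(pi * (d[rim] - core) / (radius - core)))
  w
}

place_centers <- function(n, fov, radius, overlap_fraction, max_tries = 5000) {
  margin <- radius + 1
  min_dist <- 2 * radius + 1
  lo <- c(margin, margin)
  hi <- c(fov[1] - margin, fov[2] - margin)
  if (any(hi < lo)) {
    abort("field of view too small for the configured soma radius")
  }
  n_overlap <- round(overlap_fraction * (n - 1))
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    overlap_this <- i > 1 && (i - 1) <= n_overlap
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (overlap_this) {
        # park next to the previous neuron so the two masks share pixels
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, radius, 2 * radius - 1.5)
        cand <- centers[i - 1, ] + dist * c(cos(ang), sin(ang))
        others <- setdiff(seq_len(i - 1), i - 1)
      } else {
        cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
        others <- seq_len(i - 1)
      }
      if (any(cand < lo) || any(cand > hi)) next
      ok <- TRUE
      if (length(others)) {
        dd <- sqrt(rowSums((centers[others, , drop = FALSE] -
          matrix(cand, length(others), 2, byrow = TRUE))^2))
        ok <- all(dd >= min_dist)
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed && !overlap_this) {
      # rejection sampling saturates well below hexagonal packing; fall back
      # to a jittered grid for dense fields
      grid <- jittered_grid_centers(n, lo, hi, min_dist)
      if (!is.null(grid)) {
        return(grid)
      }
    }
    if (!placed) {
      abort(paste0(
        "could not place ", n, " somas of radius ", radius, " in a ",
        fov[1], "x", fov[2], " field: density too high"
      ))
    }
  }
  centers
}

jittered_grid_centers <- function(n, lo, hi, min_dist) {
  span <- hi - lo
  ny_max <- floor(span[1] / min_dist) + 1L
  nx_max <- floor(span[2] / min_dist) + 1L
  if (ny_max * nx_max < n) {
    return(NULL)
  }
  ny <- min(ny_max, max(1L, ceiling(sqrt(n * span[1] / max(span[2], 1)))))
  nx <- ceiling(n / ny)
  if (nx > nx_max) {
    nx <- nx_max
    ny <- ceiling(n / nx)
    if (ny > ny_max) {
      return(NULL)
    }
  }
  sy <- if (ny > 1) span[1] / (ny - 1) else 0
  sx <- if (nx > 1) span[2] / (nx - 1) else 0
  jit <- max(0, min(sy, sx) - min_dist) / 2.5
  pts <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  pts <- pts[sample.int(nrow(pts), n), ]
  cbind(
    lo[1] + (pts$iy - 1) * sy + runif(n, -jit, jit),
    lo[2] + (pts$ix - 1) * sx + runif(n, -jit, jit)
  )
}

#' Generate ground-truth soma footprints
#'
#' Places `n_neurons` smooth, compact soma-like footprints (truncated
#' Gaussian profiles, ~2 x `soma_radius_px` across) in the field of view.
#' With `overlap_fraction = 0` all masks are pairwise disjoint; a positive
#' fraction forces that share of adjacent neuron pairs to overlap by at
#' least one pixel. Placement is deterministic given `seed`.
#'
#' @param n_neurons number of somas (`>= 1`).
#' @param fov_shape integer `c(H, W)` pixels.
#' @param overlap_fraction fraction of adjacent pairs that must overlap.
#' @param soma_radius_px footprint radius in pixels.
#' @param seed RNG seed.
#' @return list with `footprints` (`H x W x n` array of weights in `[0,1]`),
#'   `masks` (list of integer pixel indices, nonempty) and `centers`.
#' @examples
#' fp <- make_footprints(2, c(64, 64), seed = 1)
#' length(intersect(fp$masks[[1]], fp$masks[[2]])) # 0: disjoint
#' @export
make_footprints <- function(n_neurons, fov_shape, overlap_fraction = 0,
                            soma_radius_px = 6, seed = 1L) {
  if (n_neurons < 1) abort("need at least one neuron")
  centers <- with_seed(
    substream_seed(seed, 900),
    place_centers(n_neurons, fov_shape, soma_radius_px, overlap_fraction)
  )
  fps <- array(0, c(fov_shape[1], fov_shape[2], n_neurons))
  masks <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    img <- footprint_image(fov_shape, centers[i, ], soma_radius_px)
    fps[, , i] <- img
    masks[[i]] <- which(img > 0)
  }
  list(footprints = fps, masks = masks, centers = centers)
}
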