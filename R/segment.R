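# Single-neuron segmentation: PCA followed by spatio-temporal ICA.

#' Reduce a movie to its principal components
#'
#' Pixelwise mean-subtracted PCA of the frame stack. Spatial eigenimages are
#' orthonormal; temporal factors are the projections of every frame onto
#' them; components are ordered by decreasing variance explained. The
#' covariance is formed on whichever side (pixels or frames) is smaller.
#'
#' @param movie a [vi_movie()].
#' @param n_components number of components to keep
#'   (`<= min(T, H*W)`).
#' @param expected_neurons if supplied and larger than `n_components`, a
#'   warning is raised (the signal subspace would be truncated).
#' @return `vi_pca` list: `spatial` (`npix x k`), `temporal` (`T x k`),
#'   `var_explained`, `center`, `dim`, `frame_rate`.
#' @export
pca_reduce <- function(movie, n_components, expected_neurons = NULL) {
  d <- dim(movie)
  npix <- d[1] * d[2]
  n_t <- d[3]
  n_components <- as.integer(min(n_components, npix, n_t))
  if (!is.null(expected_neurons) && n_components < expected_neurons) {
    warn("fewer components than expected neurons: signal subspace truncated")
  }
  X <- matrix(as.numeric(movie), npix, n_t)
  center <- rowMeans(X)
  X <- X - center
  if (npix <= n_t) {
    C <- tcrossprod(X) / (n_t - 1)
    eig <- eigen(C, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    V <- eig$vectors[, seq_len(n_components), drop = FALSE]
    temporal <- crossprod(X, V)
  } else {
    G <- crossprod(X) / (n_t - 1)
    eig <- eigen(G, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    U <- eig$vectors[, seq_len(n_components), drop = FALSE]
    V <- X %*% U
    nrm <- sqrt(colSums(V^2))
    nrm[nrm == 0] <- 1
    V <- sweep(V, 2, nrm, `/`)
    temporal <- crossprod(X, V)
  }
  structure(
    list(
      spatial = V, temporal = temporal,
      var_explained = vals[seq_len(n_components)] / sum(vals),
      eigenvalues = vals, center = center,
      dim = d[1:2], frame_rate = attr(movie, "frame_rate")
    ),
    class = "vi_pca"
  )
}

# FastICA with symmetric decorrelation (tanh contrast). `x` is variables x
# samples, already centered per row. The full variable space is whitened
# (no truncation here: dimensionality is chosen upstream by the PCA) and a
# square rotation is estimated, so no source can be lost to an arbitrary
# variance ordering of the whitened directions. Returns the rotation `R`
# and whitener `K`.
fastica_symmetric <- function(x, seed, max_iter = 500, tol = 1e-5) {
  m <- ncol(x)
  k <- nrow(x)
  cv <- tcrossprod(x) / m
  eig <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(eig$values, 1e-12)), k) %*% t(eig$vectors)
  z <- K %*% x
  W <- with_seed(seed, matrix(rnorm(k^2), k))
  orthonormalize <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orthonormalize(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    g_prime <- 1 - g^2
    W_new <- (g %*% t(z)) / m - diag(rowMeans(g_prime)) %*% W
    W_new <- orthonormalize(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(R = W, K = K, converged = converged, iterations = it)
}

#' Unmix principal components into single-neuron ICs
#'
#' Spatio-temporal independent component analysis on the PCA factors: each
#' retained component contributes its spatial eigenimage (weight `mu`) and
#' its normalised temporal factor (weight `1 - mu`) to one concatenated
#' sample vector; FastICA (tanh contrast, symmetric decorrelation) then
#' rotates the components so the concatenated patterns are maximally
#' independent. `mu = 1` gives pure spatial ICA, `mu = 0` pure temporal.
#'
#' Each IC is sign-flipped so its temporal skewness is nonnegative (optical
#' spikes are positive-going) and ICs are sorted by decreasing
#' spatial-filter skewness.
#'
#' @param pca a [pca_reduce()] result.
#' @param n_ics number of independent components (`<=` retained components).
#' @param mu spatial weight in `[0, 1]` (default 0.5).
#' @param seed seed for the random orthogonal initialisation.
#' @param max_iter,tol FastICA iteration cap and convergence tolerance; if
#'   the cap is hit the best iterate is returned with `converged = FALSE`
#'   and a warning.
#' @return `vi_roiset` list: `spatial_filters` (`npix x n`), `temporal_ics`
#'   (`T x n`), per-IC `skew_spatial` / `skew_temporal` (quality scores),
#'   `converged`, `dim`, `frame_rate`.
#' @export
ica_unmix <- function(pca, n_ics, mu = 0.5, seed = 1L, max_iter = 500,
                      tol = 1e-5) {
  stopifnot(inherits(pca, "vi_pca"))
  k <- ncol(pca$spatial)
  n_ics <- as.integer(min(n_ics, k))
  if (mu < 0 || mu > 1) abort("`mu` must lie in [0, 1]")
  tnorm <- sqrt(colSums(pca$temporal^2))
  tnorm[tnorm == 0] <- 1
  temporal_unit <- sweep(pca$temporal, 2, tnorm, `/`)
  Y <- cbind(mu * t(pca$spatial), (1 - mu) * t(temporal_unit))
  Y <- Y - rowMeans(Y)
  fit <- fastica_symmetric(Y, seed, max_iter, tol)
  if (!fit$converged) {
    warn("ICA did not converge within `max_iter`; returning best iterate")
  }
  M <- fit$R %*% fit$K # k x k rotation back onto the PCA factors
  filters <- pca$spatial %*% t(M)
  traces <- temporal_unit %*% t(M)
  sk_t <- apply(traces, 2, skewness)
  flip <- ifelse(sk_t < 0, -1, 1)
  filters <- sweep(filters, 2, flip, `*`)
  traces <- sweep(traces, 2, flip, `*`)
  sk_t <- abs(sk_t)
  sk_s <- apply(filters, 2, skewness)
  # all k rotated components are computed; the n_ics most skewed spatial
  # filters (soma-like, sparse-positive) are returned
  ord <- order(sk_s, decreasing = TRUE)[seq_len(n_ics)]
  structure(
    list(
      spatial_filters = filters[, ord, drop = FALSE],
      temporal_ics = traces[, ord, drop = FALSE],
      skew_spatial = sk_s[ord], skew_temporal = sk_t[ord],
      converged = fit$converged, iterations = fit$iterations,
      masks = NULL, dim = pca$dim, frame_rate = pca$frame_rate
    ),
    class = "vi_roiset"
  )
}

#' @export
print.vi_roiset <- function(x, ...) {
  cat(sprintf(
    "<vi_roiset> %d ICs on a %dx%d px field%s\n",
    ncol(x$spatial_filters), x$dim[1], x$dim[2],
    if (is.null(x$masks)) " (no masks yet)" else ""
  ))
  invisible(x)
}

#' Threshold spatial filters into ROI masks
#'
#' A neuron's mask is the set of pixels whose filter weight is at least
#' `threshold_fraction` of the filter maximum, restricted to the largest
#' connected component (8-connectivity). ROIs whose mask comes out empty are
#' dropped with a warning.
#'
#' @param roiset a [ica_unmix()] result.
#' @param threshold_fraction fraction of the filter maximum, in `(0, 1)`.
#' @return the `vi_roiset` with a `masks` field (list of pixel index
#'   vectors) added, empty ROIs removed.
#' @export
filters_to_masks <- function(roiset, threshold_fraction = 0.5) {
  stopifnot(inherits(roiset, "vi_roiset"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)")
  }
  d <- roiset$dim
  n <- ncol(roiset$spatial_filters)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(roiset$spatial_filters[, i], d[1], d[2])
    mx <- max(f)
    if (mx <= 0) {
      masks[[i]] <- integer(0)
      next
    }
    bw <- f >= threshold_fraction * mx
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    lab <- as.integer(lab)
    if (all(lab == 0)) {
      masks[[i]] <- integer(0)
      next
    }
    sizes <- tabulate(lab)
    masks[[i]] <- which(lab == which.max(sizes))
  }
  empty <- lengths(masks) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d ROI(s) with empty masks", sum(empty)))
  }
  keep <- which(!empty)
  out <- roiset
  out$spatial_filters <- roiset$spatial_filters[, keep, drop = FALSE]
  out$temporal_ics <- roiset$temporal_ics[, keep, drop = FALSE]
  out$skew_spatial <- roiset$skew_spatial[keep]
  out$skew_temporal <- roiset$skew_temporal[keep]
  out$masks <- masks[keep]
  out
}

# Weighted raw traces, chunked over frames so the integer stack is never
# copied to double wholesale. `weights`: npix x n (zero outside each ROI).
raw_traces_matrix <- function(movie, weights, chunk = 20000L) {
  d <- dim(movie)
  npix <- d[1] * d[2]
  n_t <- d[3]
  out <- matrix(0, n_t, ncol(weights))
  for (start in seq(1L, n_t, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_t)
    X <- matrix(as.numeric(movie[, , idx]), npix, length(idx))
    out[idx, ] <- crossprod(X, weights)
  }
  out
}

#' Extract per-neuron dF/F0 traces
#'
#' For each ROI the raw fluorescence is the spatial-filter-weighted mean
#' over the mask pixels (`weighting = "filter"`, negative weights clamped to
#' zero) or the plain mask mean (`weighting = "mask"`), then converted to
#' percent dF/F0 with [compute_dff()].
#'
#' @param movie a [vi_movie()].
#' @param roiset a `vi_roiset` with masks ([filters_to_masks()]), or a list
#'   with `masks` (ground-truth masks work: uniform weights).
#' @param weighting `"filter"` or `"mask"`.
#' @inheritParams compute_dff
#' @return tibble `neuron_id`, `time_s`, `dff`, `f0`.
#' @export
extract_traces <- function(movie, roiset, weighting = c("filter", "mask"),
                           baseline_method = "sliding_percentile",
                           window_s = 10, prob = 0.2) {
  weighting <- match.arg(weighting)
  d <- dim(movie)
  npix <- d[1] * d[2]
  masks <- roiset$masks
  if (is.null(masks)) {
    abort("roiset has no masks; call filters_to_masks() first")
  }
  bad <- vapply(masks, function(m) any(m < 1 | m > npix), TRUE)
  if (any(bad)) abort("mask indices outside the field of view")
  n <- length(masks)
  W <- matrix(0, npix, n)
  for (i in seq_len(n)) {
    w <- if (weighting == "filter" && !is.null(roiset$spatial_filters)) {
      pmax(roiset$spatial_filters[masks[[i]], i], 0)
    } else {
      rep(1, length(masks[[i]]))
    }
    if (sum(w) == 0) w <- rep(1, length(masks[[i]]))
    W[masks[[i]], i] <- w / sum(w)
  }
  raw <- raw_traces_matrix(movie, W)
  times <- movie_times(movie)
  long <- tibble(
    neuron_id = rep(seq_len(n), each = length(times)),
    time_s = rep(times, n),
    f = as.numeric(raw)
  )
  compute_dff(long,
    baseline_method = baseline_method,
    window_s = window_s, prob = prob
  )
}

# Uniform-weight ROI set over ground-truth masks (for oracle comparisons).
truth_roiset <- function(truth) {
  structure(
    list(
      spatial_filters = NULL, masks = truth$masks,
      dim = dim(truth$footprints)[1:2]
    ),
    class = "vi_roiset"
  )
}
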