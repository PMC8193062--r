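# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed. Streams are fixed
# per purpose (neuron index, noise, placement, ...) so that e.g. adding a
# neuron never perturbs the spike train of another.
substream_seed <- function(master, stream) {
  master <- as.double(master)
  stream <- as.double(stream)
  ((master %% 2147483647) + 1000003 * (stream + 1)) %% 2147483629 + 1
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered moving average with reflection padding; window must be odd.
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) {
    return(x)
  }
  n <- length(x)
  if (window > n) {
    abort("moving-average window longer than the series")
  }
  h <- (window - 1L) / 2L
  padded <- c(rev(x[seq_len(h) + 1L]), x, rev(x[n - seq_len(h)]))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2))[h + seq_len(n)]
}

# Sample skewness (population form, as used for IC quality scores).
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) {
    return(NA_real_)
  }
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) {
    return(0)
  }
  mean((x - m)^3) / s2^1.5
}

# Linear-interpolated crossing time of `level` between samples i and i+1.
interp_crossing <- function(t1, t2, y1, y2, level) {
  if (y2 == y1) {
    return((t1 + t2) / 2)
  }
  t1 + (level - y1) / (y2 - y1) * (t2 - t1)
}

frame_rate_of <- function(x) {
  fr <- attr(x, "frame_rate")
  if (!is.null(fr)) {
    return(fr)
  }
  if (is.data.frame(x) && "time_s" %in% names(x)) {
    dt <- median(diff(sort(unique(x$time_s))))
    if (is.finite(dt) && dt > 0) {
      return(1 / dt)
    }
  }
  abort("cannot determine frame rate; supply `frame_rate`")
}

# Split a multi-neuron trace tibble into per-neuron tibbles (list).
split_by_neuron <- function(df) {
  if (!"neuron_id" %in% names(df)) {
    df$neuron_id <- 1L
  }
  split(df, df$neuron_id)
}
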