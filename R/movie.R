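#' Construct a voltage-imaging movie object
#'
#' A movie is a `H x W x T` array of nonnegative camera counts with frame-rate
#' and exposure metadata. Frames are the third dimension.
#'
#' @param frames numeric or integer array, dimensions `c(H, W, T)` with
#'   `T >= 3`; all counts must be nonnegative and finite.
#' @param frame_rate acquisition rate in Hz (`> 0`).
#' @param exposure_ms per-frame exposure in milliseconds.
#' @param origin `"recorded"` or `"simulated"`.
#' @return An object of class `vi_movie` (the array with metadata attributes).
#' @examples
#' m <- vi_movie(array(100, c(4, 4, 3)), frame_rate = 500)
#' dim(m)
#' @export
vi_movie <- function(frames, frame_rate, exposure_ms = 2.2,
                     origin = c("simulated", "recorded")) {
  origin <- match.arg(origin)
  if (length(dim(frames)) != 3) {
    abort("`frames` must be a 3-d array (H x W x T)")
  }
  if (dim(frames)[3] < 3) {
    abort("a movie needs at least 3 frames")
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    abort("`frame_rate` must be positive")
  }
  if (min(frames) < 0) {
    abort("camera counts must be nonnegative")
  }
  structure(frames,
    frame_rate = frame_rate, exposure_ms = exposure_ms,
    origin = origin, class = c("vi_movie", class(frames))
  )
}

#' @export
print.vi_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<vi_movie> %d x %d px, %d frames @ %g Hz (%s, exposure %g ms)\n",
    d[1], d[2], d[3], attr(x, "frame_rate"), attr(x, "origin"),
    attr(x, "exposure_ms")
  ))
  invisible(x)
}

n_frames <- function(movie) dim(movie)[3]
fov_dim <- function(movie) dim(movie)[1:2]

movie_times <- function(movie) {
  (seq_len(n_frames(movie)) - 1L) / attr(movie, "frame_rate")
}

#' Read / write movies as multi-page 16-bit grayscale TIFF
#'
#' `write_movie()` stores the frame stack as a multi-page grayscale TIFF
#' (16-bit) plus a JSON sidecar (`<path>.json`) holding frame rate, exposure
#' and origin, so that `read_movie(write_movie(m, p))` is the identity on
#' counts and metadata. `read_movie()` refuses non-grayscale input.
#'
#' @param path path to a TIFF file.
#' @param movie a [vi_movie()].
#' @return `read_movie()` returns a `vi_movie`; `write_movie()` returns `path`
#'   invisibly.
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) {
    pages <- list(pages)
  }
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2)) {
    abort("movie TIFF must be grayscale (one channel per page)")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort("ragged TIFF pages: all frames must share one shape")
  }
  frames <- array(unlist(pages, use.names = FALSE),
    dim = c(dims[[1]], length(pages))
  )
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(frame_rate = NA_real_)
  }
  if (!is.finite(meta$frame_rate %||% NA_real_)) {
    abort("missing frame-rate metadata; expected sidecar JSON next to the TIFF")
  }
  vi_movie(frames,
    frame_rate = meta$frame_rate,
    exposure_ms = meta$exposure_ms %||% 2.2,
    origin = meta$origin %||% "recorded"
  )
}

#' @rdname read_movie
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "vi_movie"))
  if (max(movie) > 65535) {
    abort("counts exceed 16-bit range")
  }
  pages <- lapply(seq_len(n_frames(movie)), function(t) {
    matrix(movie[, , t] / 65535, nrow = dim(movie)[1])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(
      frame_rate = attr(movie, "frame_rate"),
      exposure_ms = attr(movie, "exposure_ms"),
      origin = attr(movie, "origin")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Average non-overlapping blocks of `by` frames (trailing remainder dropped).
# Used to build the reduced-rate copy that segmentation operates on.
bin_movie <- function(movie, by = 3L) {
  by <- as.integer(by)
  if (by <= 1L) {
    return(movie)
  }
  d <- dim(movie)
  nb <- d[3] %/% by
  if (nb < 3) {
    abort("movie too short to bin by that factor")
  }
  npix <- d[1] * d[2]
  acc <- matrix(0, npix, nb)
  # chunk over output bins so the integer stack is never copied wholesale
  chunk <- max(1L, 2e7 %/% npix)
  for (b0 in seq(1L, nb, by = chunk)) {
    bins <- b0:min(b0 + chunk - 1L, nb)
    frames <- ((bins[1] - 1L) * by + 1L):(bins[length(bins)] * by)
    x <- matrix(as.numeric(movie[, , frames]), npix, length(frames))
    sub <- x[, seq(1L, ncol(x), by), drop = FALSE]
    for (j in seq_len(by - 1L)) {
      sub <- sub + x[, seq(1L + j, ncol(x), by), drop = FALSE]
    }
    acc[, bins] <- sub / by
  }
  dim(acc) <- c(d[1], d[2], nb)
  vi_movie(acc,
    frame_rate = attr(movie, "frame_rate") / by,
    exposure_ms = attr(movie, "exposure_ms"),
    origin = attr(movie, "origin")
  )
}
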