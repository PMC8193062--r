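# Conversion of raw fluorescence to percent dF/F0.

# Sliding-percentile baseline evaluated on a coarse grid (one knot per
# `step_s`) and linearly interpolated back to every sample; the first/last
# half-window is clamped to the nearest full window. Quantile estimation on
# every sample would cost O(T * window) for no accuracy gain at these rates.
sliding_percentile_baseline <- function(f, frame_rate, window_s = 10,
                                        prob = 0.2, step_s = 1) {
  n <- length(f)
  half <- round(window_s * frame_rate / 2)
  step <- max(1L, round(step_s * frame_rate))
  knots <- unique(c(seq(1L, n, by = step), n))
  vals <- vapply(knots, function(i) {
    lo <- max(1L, min(i - half, n - 2L * half))
    hi <- min(n, max(i + half, 1L + 2L * half))
    quantile(f[lo:hi], probs = prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(knots) == 1) {
    return(rep(vals, n))
  }
  approx(knots, vals, xout = seq_len(n), rule = 2)$y
}

#' Convert a raw fluorescence trace to percent dF/F0
#'
#' The voltage signal is expressed as the percent change of fluorescence
#' relative to a baseline estimate `F0`:
#' `dff = 100 * (F - F0) / F0`. With a brightness-increasing voltage dye,
#' action potentials appear as fast positive deflections.
#'
#' The default baseline is the 20th percentile of the raw trace in a 10-s
#' sliding window, which sparse spiking cannot inflate; `"global_mean"` and
#' `"global_percentile"` are provided for short synthetic segments.
#'
#' @param data tibble with columns `time_s` and `f` (raw counts); an optional
#'   `neuron_id` column is handled per neuron.
#' @param baseline_method one of `"sliding_percentile"`, `"global_percentile"`,
#'   `"global_mean"`.
#' @param window_s,prob sliding-window length (seconds) and percentile.
#' @return tibble with columns `neuron_id`, `time_s`, `dff` (percent) and
#'   `f0` (baseline counts).
#' @examples
#' raw <- tibble::tibble(time_s = (0:99) / 500, f = rep(1000, 100))
#' all(compute_dff(raw, "global_mean")$dff == 0)
#' @export
compute_dff <- function(data,
                        baseline_method = c(
                          "sliding_percentile", "global_percentile",
                          "global_mean"
                        ),
                        window_s = 10, prob = 0.2) {
  baseline_method <- match.arg(baseline_method)
  stopifnot(is.data.frame(data), all(c("time_s", "f") %in% names(data)))
  out <- dplyr::bind_rows(lapply(split_by_neuron(data), function(df) {
    f <- df$f
    if (!any(f > 0)) {
      abort("raw trace must be positive somewhere")
    }
    fr <- frame_rate_of(df)
    f0 <- switch(baseline_method,
      sliding_percentile = sliding_percentile_baseline(f, fr, window_s, prob),
      global_percentile = rep(quantile(f, prob, names = FALSE), length(f)),
      global_mean = rep(mean(f), length(f))
    )
    if (any(f0 <= 0)) {
      abort("baseline F0 must be positive everywhere")
    }
    tibble(
      neuron_id = df$neuron_id %||% 1L, time_s = df$time_s,
      dff = 100 * (f - f0) / f0, f0 = f0
    )
  }))
  as_tibble(out)
}

#' Remove slow photobleaching from a dF/F0 trace
#'
#' Fits a monoexponential-plus-offset decay to the raw fluorescence and
#' divides it out. Recordings acquired with shuttered illumination typically
#' show no appreciable photobleaching, so this stage is off by default in
#' [run_pipeline()]; it is provided for robustness on recordings that do
#' bleach. If the fit does not converge the input is returned unchanged with
#' a warning.
#'
#' @param data tibble with columns `time_s` and `f` (raw counts, one neuron).
#' @return tibble `time_s`, `f` with the fitted decay divided out (rescaled
#'   to the initial fitted level), plus attribute `bleach_tau_s`.
#' @export
detrend_bleach <- function(data) {
  stopifnot(is.data.frame(data), all(c("time_s", "f") %in% names(data)))
  if (nrow(data) < 100) {
    abort("need at least 100 samples to fit a bleaching trend")
  }
  if (all(data$f == 0)) {
    abort("all-zero trace: nothing to detrend")
  }
  t <- data$time_s
  f <- data$f
  # Levenberg-Marquardt: robust to the zero-residual case (bleach-free or
  # noise-free traces), where Gauss-Newton nls() aborts
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ c0 + a * exp(-t / tau),
      start = list(
        c0 = min(f), a = max(mean(head(f, 50)) - min(f), 1e-6),
        tau = max(diff(range(t)), 1)
      ),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("bleach fit did not converge; trace passed through unchanged")
    out <- data
    attr(out, "bleach_tau_s") <- Inf
    return(out)
  }
  p <- coef(fit)
  trend <- p["c0"] + p["a"] * exp(-t / p["tau"])
  out <- tibble(time_s = t, f = f / trend * trend[1])
  if ("neuron_id" %in% names(data)) out$neuron_id <- data$neuron_id
  attr(out, "bleach_tau_s") <- unname(p["tau"])
  out
}
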