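# Group comparison and detection scoring.

significance_tier <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare two groups with an unpaired two-tailed Student's t test
#'
#' Pooled-variance Student's t (use `welch = TRUE` for the unequal-variance
#' variant), two-tailed p value, per-group mean +- SD, and the conventional
#' significance tier (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). With
#' zero pooled variance, equal means give p = 1 and unequal means are
#' flagged as a degenerate p = 0 limit. No multiple-testing correction is
#' applied.
#'
#' @param data data frame in long format.
#' @param value,group column names (tidy-eval) holding the measurement and
#'   the two-level group label.
#' @param welch use the Welch statistic instead of pooled variance.
#' @return one-row tibble: group labels, `mean_a`, `sd_a`, `n_a`, `mean_b`,
#'   `sd_b`, `n_b`, `t`, `df`, `p_value`, `tier`, `degenerate`.
#' @examples
#' d <- tibble::tibble(
#'   g = rep(c("a", "b"), each = 4),
#'   y = c(1, 2, 3, 4, 3, 4, 5, 6)
#' )
#' group_compare(d, y, g)$p_value
#' @export
group_compare <- function(data, value, group, welch = FALSE) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) != 2) abort("`group` must have exactly two levels")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least two observations")
  }
  na <- length(a)
  nb <- length(b)
  ma <- mean(a)
  mb <- mean(b)
  va <- var(a)
  vb <- var(b)
  degenerate <- FALSE
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    degenerate <- ma != mb
    tval <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
  } else {
    tval <- (ma - mb) / sqrt(se2)
    p <- 2 * pt(-abs(tval), df)
  }
  tibble(
    group_a = levels(g)[1], group_b = levels(g)[2],
    mean_a = ma, sd_a = sqrt(va), n_a = na,
    mean_b = mb, sd_b = sqrt(vb), n_b = nb,
    t = tval, df = df, p_value = p,
    tier = significance_tier(p), degenerate = degenerate
  )
}

#' Score detected spikes against ground truth
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs within
#' `tolerance_ms` are accepted in order of increasing time difference, each
#' spike matching at most once. Unmatched detections are false positives,
#' unmatched truth spikes false negatives. With an empty side, the
#' undefined precision/recall is reported as 0 and flagged.
#'
#' @param detected,truth tibbles with `time_s` (optionally `neuron_id`, in
#'   which case matching is within neuron) or bare numeric vectors.
#' @param tolerance_ms matching tolerance (default 6 ms, i.e. 3 frames at
#'   500 Hz).
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `tolerance_ms`, `degenerate`.
#' @examples
#' score_detection(c(0.1, 0.5), c(0.1, 0.5))$f1 # 1
#' @export
score_detection <- function(detected, truth, tolerance_ms = 6) {
  as_tbl <- function(x) {
    if (is.data.frame(x)) {
      if (!"neuron_id" %in% names(x)) x$neuron_id <- 1L
      x
    } else {
      tibble(neuron_id = 1L, time_s = as.numeric(x))
    }
  }
  det <- as_tbl(detected)
  tru <- as_tbl(truth)
  ids <- union(unique(det$neuron_id), unique(tru$neuron_id))
  tp <- 0L
  for (id in ids) {
    dt <- sort(det$time_s[det$neuron_id == id])
    gt <- sort(tru$time_s[tru$neuron_id == id])
    if (!length(dt) || !length(gt)) next
    pairs <- expand.grid(i = seq_along(dt), j = seq_along(gt))
    pairs$d <- abs(dt[pairs$i] - gt[pairs$j])
    pairs <- pairs[pairs$d <= tolerance_ms / 1000, ]
    pairs <- pairs[order(pairs$d), ]
    used_i <- logical(length(dt))
    used_j <- logical(length(gt))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]
      j <- pairs$j[k]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE
        used_j[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(det) - tp
  fn <- nrow(tru) - tp
  degenerate <- nrow(det) == 0 || nrow(tru) == 0
  precision <- if (nrow(det)) tp / nrow(det) else 0
  recall <- if (nrow(tru)) tp / nrow(tru) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble(
    tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
    f1 = f1, tolerance_ms = tolerance_ms, degenerate = degenerate
  )
}

#' Match recovered ROIs to ground-truth masks
#'
#' Greedy one-to-one assignment by decreasing Jaccard overlap of the pixel
#' masks; pairs with zero overlap are never matched.
#'
#' @param masks,truth_masks lists of pixel-index vectors.
#' @return tibble `roi`, `truth_id`, `jaccard`, one row per matched pair.
#' @export
match_rois <- function(masks, truth_masks) {
  if (!length(masks) || !length(truth_masks)) {
    return(tibble(roi = integer(0), truth_id = integer(0), jaccard = numeric(0)))
  }
  J <- matrix(0, length(masks), length(truth_masks))
  for (i in seq_along(masks)) {
    for (j in seq_along(truth_masks)) {
      J[i, j] <- length(intersect(masks[[i]], truth_masks[[j]])) /
        length(union(masks[[i]], truth_masks[[j]]))
    }
  }
  res <- list()
  Jw <- J
  repeat {
    m <- which.max(Jw)
    if (Jw[m] <= 0) break
    i <- (m - 1) %% nrow(Jw) + 1
    j <- (m - 1) %/% nrow(Jw) + 1
    res[[length(res) + 1]] <- tibble(roi = i, truth_id = j, jaccard = J[i, j])
    Jw[i, ] <- -1
    Jw[, j] <- -1
  }
  dplyr::bind_rows(res)
}
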