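#' Detect calcium-ratio rise onsets
#'
#' An onset is an upward crossing of `rise_threshold` (previous point
#' strictly below, current point above). Crossings closer than
#' `min_separation_s` to the previous accepted onset are suppressed
#' (debounce). The same 1.10 normalized-ratio level used for
#' elevated/basal classification is the default, for internal consistency.
#'
#' @param norm_ratio Normalized ratio series.
#' @param t_s Times in seconds, same length.
#' @param rise_threshold Crossing level (default 1.10).
#' @param min_separation_s Debounce interval (default 30 s).
#' @return Numeric vector of onset times (possibly empty).
#' @export
detect_ratio_rises <- function(norm_ratio, t_s, rise_threshold = 1.10,
                               min_separation_s = 30) {
  if (length(norm_ratio) != length(t_s)) stop("length mismatch")
  up <- which(norm_ratio[-1L] > rise_threshold &
              norm_ratio[-length(norm_ratio)] <= rise_threshold) + 1L
  onsets <- numeric(0)
  for (i in up) {
    if (!length(onsets) || t_s[i] - onsets[length(onsets)] >= min_separation_s) {
      onsets <- c(onsets, t_s[i])
    }
  }
  onsets
}

#' Calcium-rise-triggered average of instantaneous velocity
#'
#' Velocity segments around each onset are resampled onto a common
#' relative-time grid by nearest frame (no interpolation; frame intervals
#' of 5-20 s make interpolation speculative) and averaged across events.
#' The velocity minimum is located on the mean curve within `[0, +20]` s,
#' and compared against each event's own baseline (mean velocity over the
#' baseline window) by a two-tailed paired t-test.
#'
#' @param ts A [track_set()] whose tracks carry green/red series, or a
#'   list of `list(t_s=, velocity=, onsets=)` entries.
#' @param onsets Optional list of per-track onset-time vectors; when
#'   `NULL`, onsets are detected with [detect_ratio_rises()] on each
#'   track's normalized ratio trace.
#' @param window Relative-time window `c(lo, hi)` in seconds
#'   (default `c(-40, 40)`).
#' @param baseline Baseline window in seconds (default `c(-30, -10)`;
#'   must precede 0).
#' @param rise_threshold,min_separation_s Passed to [detect_ratio_rises()].
#' @return List of class `"aligned_average"`: `rel_time_s`,
#'   `mean_velocity`, `sem_velocity`, `mean_norm_ratio`, `n_events`,
#'   `t_min_s`, `baseline`, `p_value`, and the per-event matrices.
#' @export
event_triggered_average <- function(ts, onsets = NULL, window = c(-40, 40),
                                    baseline = c(-30, -10),
                                    rise_threshold = 1.10,
                                    min_separation_s = 30) {
  if (baseline[2L] > 0) stop("baseline window must precede the onset")
  stopifnot(inherits(ts, "stopgo_trackset"))
  dt <- attr(ts, "dt_s")
  grid <- seq(ceiling(window[1L] / dt) * dt, floor(window[2L] / dt) * dt, by = dt)
  seg_v <- list(); seg_r <- list(); base <- numeric(0)
  for (i in seq_along(ts)) {
    tr <- ts[[i]]
    v <- instantaneous_velocities(tr)
    vt <- tr$t_s[-length(tr$t_s)]  # velocity paired with earlier frame
    nr <- NULL
    if (!is.null(tr$green) && !is.null(tr$red)) {
      nr <- ratio_trace(tr$t_s, tr$green, tr$red)$norm_ratio
    }
    ons <- if (!is.null(onsets)) onsets[[i]] else {
      if (is.null(nr)) stop("track has no green/red series and no onsets were supplied")
      detect_ratio_rises(nr, tr$t_s, rise_threshold, min_separation_s)
    }
    for (o in ons) {
      rel_v <- vt - o
      vi <- vapply(grid, function(gp) {
        j <- which.min(abs(rel_v - gp))
        if (abs(rel_v[j] - gp) <= dt / 2 + 1e-9) v[j] else NA_real_
      }, numeric(1))
      bsel <- rel_v >= baseline[1L] & rel_v <= baseline[2L]
      psel <- rel_v > 0 & rel_v <= window[2L]
      if (!any(bsel) || !any(psel)) next  # onset lacks baseline or post samples
      seg_v[[length(seg_v) + 1L]] <- vi
      base <- c(base, mean(v[bsel]))
      if (!is.null(nr)) {
        rel_r <- tr$t_s - o
        seg_r[[length(seg_r) + 1L]] <- vapply(grid, function(gp) {
          j <- which.min(abs(rel_r - gp))
          if (abs(rel_r[j] - gp) <= dt / 2 + 1e-9) nr[j] else NA_real_
        }, numeric(1))
      }
    }
  }
  if (!length(seg_v)) stop("no qualifying events (each onset needs baseline and post-onset samples)")
  V <- do.call(rbind, seg_v)
  mean_v <- colMeans(V, na.rm = TRUE)
  sem_v <- apply(V, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  mean_r <- if (length(seg_r)) colMeans(do.call(rbind, seg_r), na.rm = TRUE) else NULL
  sel <- which(grid >= 0 & grid <= 20)
  t_min_s <- grid[sel][which.min(mean_v[sel])]
  vmin <- V[, which(grid == t_min_s)]
  ok <- !is.na(vmin) & !is.na(base)
  d <- vmin[ok] - base[ok]
  p <- if (length(d) < 2L) {
    NA_real_
  } else if (stats::sd(d) <= 1e-8 * max(abs(mean(d)), 1e-12)) {
    # degenerate paired differences: identical shifts across every event
    if (abs(mean(d)) < 1e-12) 1 else 0
  } else {
    stats::t.test(d)$p.value
  }
  structure(list(rel_time_s = grid, mean_velocity = mean_v, sem_velocity = sem_v,
                 mean_norm_ratio = mean_r, n_events = nrow(V), t_min_s = t_min_s,
                 baseline = baseline, p_value = p,
                 velocity_segments = V, baseline_means = base),
            class = "aligned_average")
}

#' @export
print.aligned_average <- function(x, ...) {
  cat(sprintf("<aligned average: %d events, velocity minimum at %+.3g s, p = %.3g vs baseline [%g, %g] s>\n",
              x$n_events, x$t_min_s, x$p_value, x$baseline[1L], x$baseline[2L]))
  invisible(x)
}

#' Pooled velocity-ratio scatter and Spearman correlation
#'
#' Pools all (instantaneous velocity, normalized ratio) pairs across the
#' tracks of a set (velocity paired with the ratio at the earlier frame of
#' each displacement interval) and computes Spearman's rank correlation
#' with a two-tailed p value.
#'
#' @param ts A [track_set()] with green/red series.
#' @param use_norm Use the normalized ratio (default) or the raw
#'   bleach-corrected ratio.
#' @return List with `pairs` (data frame `velocity_um_min`, `ratio`,
#'   `cell_id`), `rho`, `p_value`, `n`.
#' @export
velocity_ratio_scatter <- function(ts, use_norm = TRUE) {
  stopifnot(inherits(ts, "stopgo_trackset"))
  pairs <- do.call(rbind, lapply(ts, function(tr) {
    if (is.null(tr$green) || is.null(tr$red)) return(NULL)
    rt <- ratio_trace(tr$t_s, tr$green, tr$red)
    v <- instantaneous_velocities(tr)
    r <- if (use_norm) rt$norm_ratio else rt$ratio
    data.frame(velocity_um_min = v, ratio = r[-length(r)], cell_id = tr$cell_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) < 10L) stop("need at least 10 paired points")
  near_const <- function(x) stats::sd(x) <= 1e-10 * max(mean(abs(x)), 1e-300)
  if (near_const(pairs$velocity_um_min) || near_const(pairs$ratio)) {
    stop("correlation undefined: one series is constant")
  }
  ct <- suppressWarnings(stats::cor.test(pairs$velocity_um_min, pairs$ratio,
                                         method = "spearman", exact = FALSE))
  list(pairs = pairs, rho = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(pairs))
}
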