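#' Correct linear photobleaching of the red channel
#'
#' Fits a least-squares line `a + b * t` to the raw red (tdTomato) trace
#' and divides by the normalized fitted line: `R_corr = R_raw /
#' (1 + (b / a) * t)`. A flat-trend trace is returned unchanged and the
#' corrected trace has zero linear trend; the correction is multiplicative,
#' matching a photobleaching model in which a fixed fraction of
#' fluorophores is lost per unit time (linearized over a recording).
#'
#' @param R_raw Numeric vector of raw red intensities (positive).
#' @param t_s Times in seconds, same length.
#' @return Corrected red intensities.
#' @export
bleach_correct <- function(R_raw, t_s) {
  if (length(R_raw) < 5L) stop("need at least 5 frames to estimate a bleach trend")
  if (length(R_raw) != length(t_s)) stop("R_raw and t_s lengths differ")
  if (any(R_raw < 0)) stop("negative intensities")
  fit <- stats::lm.fit(cbind(1, t_s), R_raw)
  a <- fit$coefficients[[1L]]
  b <- fit$coefficients[[2L]]
  if (a <= 0) stop("bleach fit gave non-positive intercept; cannot correct")
  decline <- -b / a * (max(t_s) - min(t_s))
  if (decline > 0.6) {
    warning(sprintf("fitted red decline of %.0f%% exceeds the 20-30%% regime this correction is meant for",
                    100 * decline))
  }
  R_raw / (1 + (b / a) * t_s)
}

#' Build a ratiometric calcium trace from green/red series
#'
#' Computes the bleach-corrected G/R ratio and the ratio normalized to
#' `R0`, the mean of the first five ratios of the trace.
#'
#' @param t_s Times (s).
#' @param G Total green (GCaMP6f) intensities.
#' @param R_raw Total red (tdTomato) intensities.
#' @param correct_bleach Apply [bleach_correct()] to the red channel
#'   (default `TRUE`).
#' @return A data frame of class `"ratio_trace"` with columns `t_s`, `G`,
#'   `R_raw`, `R_corr`, `ratio`, `norm_ratio`, and attribute `R0`.
#' @export
ratio_trace <- function(t_s, G, R_raw, correct_bleach = TRUE) {
  n <- length(t_s)
  if (length(G) != n || length(R_raw) != n) stop("series lengths differ")
  if (n < 5L) stop("need at least 5 frames for R0 normalization")
  if (any(G < 0) || any(R_raw < 0)) stop("negative intensities")
  R_corr <- if (correct_bleach) bleach_correct(R_raw, t_s) else R_raw
  ratio <- G / R_corr
  R0 <- mean(ratio[1:5])
  if (!is.finite(R0) || R0 == 0) stop("R0 is zero or undefined; cannot normalize")
  out <- data.frame(t_s = t_s, G = G, R_raw = R_raw, R_corr = R_corr,
                    ratio = ratio, norm_ratio = ratio / R0)
  attr(out, "R0") <- R0
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Normalize a ratio series to the mean of its first five points
#'
#' @param ratio Numeric vector of G/R ratios (first five define `R0`).
#' @return `ratio / R0`.
#' @export
normalize_ratio <- function(ratio) {
  if (length(ratio) < 5L) stop("need at least 5 frames for R0 normalization")
  R0 <- mean(ratio[1:5])
  if (!is.finite(R0) || R0 == 0) stop("R0 is zero or undefined; cannot normalize")
  ratio / R0
}

#' Classify time points as calcium-elevated
#'
#' Elevated iff the normalized ratio strictly exceeds `ratio_threshold`
#' (default 1.10; a point exactly at the threshold is basal).
#'
#' @param norm_ratio Normalized ratio series.
#' @param ratio_threshold Threshold on the normalized ratio.
#' @return Logical vector.
#' @export
classify_elevated <- function(norm_ratio, ratio_threshold = 1.10) {
  norm_ratio > ratio_threshold
}

#' Quadrant occupancy of the velocity-ratio scatter
#'
#' Fractions of paired time points in the four quadrants defined by a
#' velocity threshold (default 10 um/min) and a normalized-ratio threshold
#' (default 1.10), both strict.
#'
#' @param velocity Instantaneous velocities (um/min).
#' @param norm_ratio Normalized ratios, same length.
#' @param v_threshold,r_threshold Quadrant boundaries.
#' @return Named numeric vector `c(elevated_fast, elevated_slow,
#'   basal_fast, basal_slow)` summing to 1.
#' @export
quadrant_fractions <- function(velocity, norm_ratio, v_threshold = 10,
                               r_threshold = 1.10) {
  if (length(velocity) != length(norm_ratio)) stop("length mismatch")
  elev <- norm_ratio > r_threshold
  fast <- velocity > v_threshold
  c(elevated_fast = mean(elev & fast),
    elevated_slow = mean(elev & !fast),
    basal_fast = mean(!elev & fast),
    basal_slow = mean(!elev & !fast))
}

#' Mean velocity during elevated versus basal calcium
#'
#' State-conditional means (with SEM) of instantaneous velocity, pooled
#' over all points and per cell. Cells lacking one state contribute only
#' to the other.
#'
#' @param velocity Instantaneous velocities (um/min), or a list of
#'   per-cell velocity vectors.
#' @param elevated Logical elevated mask, matching `velocity`'s structure.
#' @return List with `pooled` (data frame: state, n, mean, sem) and, when
#'   given per-cell lists, `per_cell` (data frame of per-cell state means).
#' @export
velocity_by_ca_state <- function(velocity, elevated) {
  if (is.list(velocity)) {
    if (!is.list(elevated) || length(elevated) != length(velocity)) {
      stop("elevated must mirror the per-cell structure of velocity")
    }
    per_cell <- do.call(rbind, lapply(seq_along(velocity), function(i) {
      v <- velocity[[i]]; e <- elevated[[i]]
      data.frame(cell = i,
                 mean_elevated = if (any(e)) mean(v[e]) else NA_real_,
                 mean_basal = if (any(!e)) mean(v[!e]) else NA_real_)
    }))
    v <- unlist(velocity); e <- unlist(elevated)
  } else {
    per_cell <- NULL
    v <- velocity; e <- as.logical(elevated)
  }
  if (length(v) != length(e)) stop("length mismatch")
  if (!any(e) && !any(!e)) stop("no points in either state")
  if (!any(e) || !any(!e)) stop("need at least one point in each state for pooled output")
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  pooled <- data.frame(state = c("elevated", "basal"),
                       n = c(sum(e), sum(!e)),
                       mean = c(mean(v[e]), mean(v[!e])),
                       sem = c(sem(v[e]), sem(v[!e])))
  list(pooled = pooled, per_cell = per_cell)
}
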