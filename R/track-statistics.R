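#' Instantaneous velocities of a track
#'
#' Frame-to-frame speed using all available spatial dimensions, in
#' micrometres per minute. Element `i` is the displacement between frames
#' `i` and `i + 1` divided by the elapsed time; no smoothing is applied.
#'
#' @param tr A [track()].
#' @return Numeric vector of length `n_frames - 1`, in um/min.
#' @export
instantaneous_velocities <- function(tr) {
  stopifnot(inherits(tr, "stopgo_track"))
  dt <- diff(tr$t_s)
  if (any(dt == 0)) stop("duplicate timestamps")
  disp <- sqrt(rowSums(diff(tr$pos_um)^2))
  60 * disp / dt
}

#' Arrest coefficient
#'
#' Fraction of a track's steps with instantaneous velocity strictly below
#' `threshold_um_min` (default 2 um/min), the conventional measure of
#' pausing propensity for lymphocytes.
#'
#' @param tr A [track()].
#' @param threshold_um_min Positive velocity threshold in um/min.
#' @return A fraction in `[0, 1]`.
#' @export
arrest_coefficient <- function(tr, threshold_um_min = 2) {
  if (!is.numeric(threshold_um_min) || threshold_um_min <= 0) {
    stop("threshold must be positive")
  }
  v <- instantaneous_velocities(tr)
  mean(v < threshold_um_min)
}

#' Pause segment durations
#'
#' Maximal runs of consecutive sub-threshold instantaneous velocities;
#' each run of `k` steps at frame interval `dt` is a pause of `k * dt`
#' seconds.
#'
#' @inheritParams arrest_coefficient
#' @return Numeric vector of pause durations in seconds (possibly empty).
#' @export
pause_segments <- function(tr, threshold_um_min = 2) {
  if (!is.numeric(threshold_um_min) || threshold_um_min <= 0) {
    stop("threshold must be positive")
  }
  v <- instantaneous_velocities(tr)
  dt <- diff(tr$t_s)
  r <- rle(v < threshold_um_min)
  if (!any(r$values)) return(numeric(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  vapply(idx, function(i) sum(dt[starts[i]:ends[i]]), numeric(1))
}

#' Coefficient of variation of instantaneous velocity
#'
#' Per-cell standard deviation of instantaneous velocity divided by its
#' mean, in percent. The sample (n - 1) standard deviation is used.
#'
#' @param tr A [track()].
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(tr) {
  v <- instantaneous_velocities(tr)
  m <- mean(v)
  if (m <= 0) stop("coefficient of variation undefined: mean velocity is zero")
  100 * stats::sd(v) / m
}

#' Turn angles between successive displacements
#'
#' Angle in degrees (0 = straight ahead, 180 = direct reversal) between
#' successive displacement vectors. Steps shorter than `min_step_um` are
#' skipped (their heading is noise-dominated) and the angle spans the gap.
#'
#' @param tr A [track()].
#' @param min_step_um Minimum step length in um for a displacement to
#'   define a heading (default 0.5).
#' @return Numeric vector of angles in `[0, 180]` degrees.
#' @export
turn_angles <- function(tr, min_step_um = 0.5) {
  stopifnot(inherits(tr, "stopgo_track"))
  if (length(tr$t_s) < 3L) stop("need at least 3 frames for turn angles")
  d <- diff(tr$pos_um)
  len <- sqrt(rowSums(d^2))
  keep <- which(len >= min_step_um)
  if (length(keep) < 2L) return(numeric(0))
  a <- d[keep[-length(keep)], , drop = FALSE]
  b <- d[keep[-1L], , drop = FALSE]
  cosang <- rowSums(a * b) / (len[keep[-length(keep)]] * len[keep[-1L]])
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Per-track motility summary
#'
#' @inheritParams arrest_coefficient
#' @return A one-row data frame with `cell_id`, `mean_velocity_um_min`,
#'   `max_inst_velocity_um_min`, `min_inst_velocity_um_min`,
#'   `arrest_coefficient`, `cov_percent`, `n_frames`, plus the pause
#'   durations as a list column `pause_durations_s`.
#' @export
motility_summary <- function(tr, threshold_um_min = 2) {
  v <- instantaneous_velocities(tr)
  out <- data.frame(cell_id = tr$cell_id,
                    mean_velocity_um_min = mean(v),
                    max_inst_velocity_um_min = max(v),
                    min_inst_velocity_um_min = min(v),
                    arrest_coefficient = mean(v < threshold_um_min),
                    cov_percent = if (mean(v) > 0) 100 * stats::sd(v) / mean(v) else NA_real_,
                    n_frames = length(tr$t_s),
                    stringsAsFactors = FALSE)
  out$pause_durations_s <- list(pause_segments(tr, threshold_um_min))
  out
}

#' Summarize every track in a set
#'
#' @param ts A [track_set()].
#' @inheritParams arrest_coefficient
#' @return Data frame, one row per track, with a `group` column.
#' @export
summarize_tracks <- function(ts, threshold_um_min = 2) {
  stopifnot(inherits(ts, "stopgo_trackset"))
  out <- do.call(rbind, lapply(ts, motility_summary, threshold_um_min = threshold_um_min))
  out$group <- attr(ts, "group")
  out
}

#' Directionality ratio curve and decay time
#'
#' Per track, the directionality ratio at elapsed time `t_i` is the net
#' displacement from the start divided by the cumulative path length up to
#' `t_i`; it starts at 1 and decays as paths meander. The track-averaged
#' curve is fitted with `r(t) = r_inf + (1 - r_inf) * exp(-t / tau)` by
#' nonlinear least squares with `r_inf` constrained to `[0, 1]`.
#'
#' @param ts A [track_set()].
#' @param fit Logical; fit the exponential decay (default `TRUE`).
#' @return List with `curve` (data frame: `elapsed_s`, `ratio`, `n`, `sem`),
#'   `tau_s`, `r_inf`, and `fit` (the `nls` object or `NULL`).
#' @export
directionality_ratio_curve <- function(ts, fit = TRUE) {
  stopifnot(inherits(ts, "stopgo_trackset"))
  percell <- lapply(ts, function(tr) {
    disp <- sqrt(rowSums((tr$pos_um[-1L, , drop = FALSE] -
                          matrix(tr$pos_um[1L, ], nrow(tr$pos_um) - 1L,
                                 ncol(tr$pos_um), byrow = TRUE))^2))
    path <- cumsum(sqrt(rowSums(diff(tr$pos_um)^2)))
    ratio <- ifelse(path > 0, disp / path, NA_real_)
    list(elapsed = tr$t_s[-1L] - tr$t_s[1L], ratio = ratio)
  })
  # align by elapsed-time index (uniform dt across the set)
  nmax <- max(vapply(percell, function(p) length(p$ratio), integer(1)))
  mat <- matrix(NA_real_, length(percell), nmax)
  for (i in seq_along(percell)) {
    mat[i, seq_along(percell[[i]]$ratio)] <- percell[[i]]$ratio
  }
  longest <- which.max(vapply(percell, function(p) length(p$elapsed), integer(1)))
  elapsed <- percell[[longest]]$elapsed
  n <- colSums(!is.na(mat))
  ratio <- colMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  curve <- data.frame(elapsed_s = elapsed, ratio = ratio, n = n, sem = sem)
  tau <- NA_real_; r_inf <- NA_real_; fobj <- NULL
  if (isTRUE(fit)) {
    f <- fit_directionality_decay(curve$elapsed_s, curve$ratio)
    tau <- f$tau_s; r_inf <- f$r_inf; fobj <- f$fit
  }
  list(curve = curve, tau_s = tau, r_inf = r_inf, fit = fobj)
}

#' Fit the exponential directionality decay model
#'
#' Least-squares fit of `r(t) = r_inf + (1 - r_inf) * exp(-t / tau)` with
#' `r_inf` in `[0, 1]` and `tau > 0`. Used both on measured curves and on
#' analytic persistent-random-walk decay curves (as an independent oracle).
#'
#' @param elapsed_s Elapsed times (s).
#' @param ratio Directionality ratios.
#' @return List with `tau_s`, `r_inf` and the underlying `nls` fit (or
#'   `NULL` if the optimizer-based fallback was used). Fit failures raise
#'   an error carrying the model diagnostics.
#' @export
fit_directionality_decay <- function(elapsed_s, ratio) {
  ok <- is.finite(elapsed_s) & is.finite(ratio)
  d <- data.frame(t = elapsed_s[ok], r = ratio[ok])
  if (nrow(d) < 4L) stop("too few points to fit directionality decay")
  tau0 <- max(d$t[which(d$r < 1 - (1 - min(d$r)) * 0.632)][1L], d$t[2L], na.rm = TRUE)
  fit <- tryCatch(
    stats::nls(r ~ rinf + (1 - rinf) * exp(-t / tau), data = d,
               start = list(rinf = max(min(d$r) * 0.9, 1e-3), tau = tau0),
               lower = c(rinf = 0, tau = 1e-6), upper = c(rinf = 1, tau = Inf),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to a bounded Nelder-Mead on the same objective
    obj <- function(p) {
      rinf <- stats::plogis(p[1L]); tau <- exp(p[2L])
      sum((d$r - (rinf + (1 - rinf) * exp(-d$t / tau)))^2)
    }
    op <- stats::optim(c(0, log(tau0)), obj)
    if (op$convergence != 0) {
      stop("directionality decay fit failed: ", conditionMessage(fit),
           " (fallback optim convergence code ", op$convergence, ")")
    }
    return(list(tau_s = exp(op$par[2L]), r_inf = stats::plogis(op$par[1L]), fit = NULL))
  }
  cf <- stats::coef(fit)
  list(tau_s = unname(cf["tau"]), r_inf = unname(cf["rinf"]), fit = fit)
}

#' Mean-squared displacement curve and motility coefficient
#'
#' MSD at lag `k` frames is averaged over all ordered frame pairs with that
#' lag within a track (overlapping windows), then averaged across tracks.
#' The motility coefficient `M` comes from a zero-intercept linear fit of
#' MSD against lag time over the first quarter of available lags, using the
#' random-walk relation `MSD = 2 * dim * M * t` (2D: `4Mt`, 3D: `6Mt`).
#'
#' @param ts A [track_set()] with a common frame interval.
#' @param fit_fraction Fraction of the shortest lags used in the fit
#'   (default 0.25).
#' @return List with `curve` (data frame: `lag_min`, `msd_um2`, `n_tracks`,
#'   `sem`), `motility_coefficient_um2_min`, `slope_um2_min`, `dim`, and
#'   `fit_lags_min`.
#' @export
msd_curve <- function(ts, fit_fraction = 0.25) {
  stopifnot(inherits(ts, "stopgo_trackset"))
  dts <- vapply(ts, function(tr) stats::median(diff(tr$t_s)), numeric(1))
  if ((max(dts) - min(dts)) > 0.01 * stats::median(dts)) {
    stop("mixed frame intervals across tracks; MSD lags would not align")
  }
  dt_min <- stats::median(dts) / 60
  nmax <- max(vapply(ts, function(tr) length(tr$t_s), integer(1)))
  mat <- matrix(NA_real_, length(ts), nmax - 1L)
  for (i in seq_along(ts)) {
    mat[i, seq_len(length(ts[[i]]$t_s) - 1L)] <- track_msd(ts[[i]]$pos_um)
  }
  msd <- colMeans(mat, na.rm = TRUE)
  n <- colSums(!is.na(mat))
  sem <- apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  lag_min <- seq_len(nmax - 1L) * dt_min
  nfit <- max(2L, floor((nmax - 1L) * fit_fraction))
  sel <- seq_len(nfit)
  slope <- sum(msd[sel] * lag_min[sel], na.rm = TRUE) / sum(lag_min[sel]^2)
  dim <- attr(ts, "ndim")
  list(curve = data.frame(lag_min = lag_min, msd_um2 = msd, n_tracks = n, sem = sem),
       motility_coefficient_um2_min = slope / (2 * dim),
       slope_um2_min = slope, dim = dim, fit_lags_min = lag_min[sel])
}

# Per-track MSD over all overlapping frame pairs, vectorized per lag.
track_msd <- function(pos) {
  n <- nrow(pos)
  vapply(seq_len(n - 1L), function(k) {
    d <- pos[(k + 1L):n, , drop = FALSE] - pos[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Histogram of per-track mean velocities
#'
#' @param ts A [track_set()].
#' @param bin_um_min Bin width in um/min (default 1).
#' @param threshold_um_min Threshold for `fraction_below` (strict `<`,
#'   default 7 um/min as used for slow-cell fractions).
#' @return List with `breaks`, `fraction` (bin fractions summing to 1),
#'   `mean_velocities`, and `fraction_below`.
#' @export
velocity_histogram <- function(ts, bin_um_min = 1, threshold_um_min = 7) {
  stopifnot(inherits(ts, "stopgo_trackset"))
  means <- vapply(ts, function(tr) mean(instantaneous_velocities(tr)), numeric(1))
  breaks <- seq(0, (floor(max(means) / bin_um_min) + 1) * bin_um_min, by = bin_um_min)
  counts <- tabulate(findInterval(means, breaks), nbins = length(breaks) - 1L)
  list(breaks = breaks, fraction = counts / length(means),
       mean_velocities = means,
       fraction_below = mean(means < threshold_um_min))
}
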