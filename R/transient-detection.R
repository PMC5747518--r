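#' Mask stationary autofluorescent structures
#'
#' Autofluorescent bodies are bright in (almost) every frame, so their
#' per-pixel temporal 10th percentile stays high, whereas transients and
#' passing cells only raise a pixel briefly. Pixels whose green temporal
#' 10th percentile exceeds a robust threshold (median + `k` x MAD-derived
#' SD of the percentile image) are marked stationary-bright and set to the
#' image background level in both channels.
#'
#' @param stack An [image_stack()] with at least 20 frames.
#' @param k Robust threshold multiplier (default 5).
#' @return List with `stack` (masked copy) and `mask` (logical ny x nx
#'   matrix of masked pixels, for audit).
#' @export
mask_autofluorescence <- function(stack, k = 5) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$green)
  if (d[3L] < 20L) stop("need at least 20 frames to estimate a temporal baseline")
  q10 <- .pixel_time_quantile(stack$green, d, 0.1)
  thr <- stats::median(q10) + k * stats::mad(q10)
  mask <- q10 > thr
  if (any(mask)) {
    bg_g <- as.integer(round(stats::median(stack$green)))
    bg_r <- as.integer(round(stats::median(stack$red)))
    idx <- which(mask)  # pixel indices within one frame
    plane <- d[1L] * d[2L]
    all_idx <- as.vector(outer(idx, (seq_len(d[3L]) - 1L) * plane, `+`))
    stack$green[all_idx] <- bg_g
    stack$red[all_idx] <- bg_r
  }
  list(stack = stack, mask = mask)
}

#' Detect calcium transients in an XY-T stack
#'
#' Connected components (26-connectivity, time as the third axis) of green
#' voxels strictly above an intensity threshold. Components are kept when
#' they contain strictly more than `min_voxels` voxels AND their inclusive
#' time extent is at least `min_duration_s`; each surviving component is
#' measured with [ellipsoid_metrics()] and classified with
#' [classify_event()].
#'
#' @param stack A (masked) [image_stack()].
#' @param threshold `"auto"` (default: median + `k_mad` x MAD-derived SD of
#'   the green channel, a reproducible stand-in for manual thresholding) or
#'   an absolute intensity.
#' @param min_voxels Voxel-count filter; components must exceed it
#'   (strict `>`; default 10).
#' @param min_duration_s Minimum inclusive duration in seconds (default 2;
#'   `>=`).
#' @param k_mad Multiplier for the automatic threshold (default 5).
#' @param area_threshold_um2 Sparkle / cell-wide boundary passed to
#'   [classify_event()] (default 20).
#' @return Data frame of class `"transient_events"`, one row per event:
#'   `id`, `centroid_x_um`, `centroid_y_um`, `onset_s`, `duration_s`,
#'   `x_diameter_um`, `y_diameter_um`, `t_diameter_s`, `area_um2`,
#'   `n_voxels`, `integrated_intensity`, `integrated_norm_intensity`
#'   (green-SD units), `klass`. Attributes: `threshold`, `green_sd`.
#' @export
detect_transients <- function(stack, threshold = "auto", min_voxels = 10L,
                              min_duration_s = 2, k_mad = 5,
                              area_threshold_um2 = 20) {
  stopifnot(inherits(stack, "image_stack"))
  g <- stack$green
  d <- dim(g)
  gn <- as.numeric(g)
  med <- stats::median(gn)
  sd_g <- stats::sd(gn)
  if (identical(threshold, "auto")) {
    threshold <- med + k_mad * stats::mad(gn, center = med)
  }
  rm(gn)
  if (threshold <= med) {
    warning(sprintf("threshold %.3g is at or below the image background mode %.3g; expect spurious events",
                    threshold, med))
  }
  lab <- .label_components(g, d, threshold)
  empty <- data.frame(id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), onset_s = numeric(0),
                      duration_s = numeric(0), x_diameter_um = numeric(0),
                      y_diameter_um = numeric(0), t_diameter_s = numeric(0),
                      area_um2 = numeric(0), n_voxels = integer(0),
                      integrated_intensity = numeric(0),
                      integrated_norm_intensity = numeric(0),
                      klass = character(0), stringsAsFactors = FALSE)
  if (!length(lab$index)) {
    return(structure(empty, threshold = threshold, green_sd = sd_g,
                     class = c("transient_events", "data.frame")))
  }
  idx0 <- lab$index - 1L
  plane <- d[1L] * d[2L]
  vox <- data.frame(label = lab$label,
                    y = idx0 %% d[1L],
                    x = (idx0 %/% d[1L]) %% d[2L],
                    t = idx0 %/% plane,
                    intensity = as.numeric(g[lab$index]))
  comps <- split(vox, vox$label)
  rows <- lapply(comps, function(cm) {
    n_vox <- nrow(cm)
    t_ext <- (max(cm$t) - min(cm$t) + 1L) * stack$dt_s
    if (!(n_vox > min_voxels) || t_ext < min_duration_s) return(NULL)
    m <- ellipsoid_metrics(cm, pixel_um = stack$pixel_um, dt_s = stack$dt_s)
    data.frame(id = cm$label[1L], centroid_x_um = m$centroid_x_um,
               centroid_y_um = m$centroid_y_um, onset_s = min(cm$t) * stack$dt_s,
               duration_s = m$duration_s, x_diameter_um = m$x_diameter_um,
               y_diameter_um = m$y_diameter_um, t_diameter_s = m$t_diameter_s,
               area_um2 = m$area_um2, n_voxels = n_vox,
               integrated_intensity = sum(cm$intensity),
               integrated_norm_intensity = sum(cm$intensity) / sd_g,
               klass = NA_character_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out$klass <- vapply(out$area_um2, function(a) {
      classify_event(a, area_threshold_um2)
    }, character(1))
    out <- out[order(out$onset_s, out$centroid_x_um), , drop = FALSE]
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  structure(out, threshold = threshold, green_sd = sd_g,
            class = c("transient_events", "data.frame"))
}

#' Ellipsoid metrics of a spatiotemporal component
#'
#' Diameters are four times the square root of the eigenvalues of the
#' intensity-weighted spatial covariance (the ellipse-equivalent diameter;
#' for a uniform disc this recovers the true diameter exactly), converted
#' to micrometres; the event area is `pi * (dx / 2) * (dy / 2)`. Duration
#' uses the inclusive frame extent, `(t_max - t_min + 1) * dt_s`, so a
#' 4-frame event at 0.5 s per frame lasts 2.0 s. Degenerate single-voxel
#' extents are floored at one voxel size.
#'
#' @param component Data frame with columns `x`, `y`, `t` (0-based voxel
#'   coordinates) and `intensity`.
#' @param pixel_um Pixel size (um); `dt_s` frame interval (s).
#' @param dt_s Frame interval in seconds.
#' @return List with `centroid_x_um`, `centroid_y_um`, `x_diameter_um`,
#'   `y_diameter_um`, `t_diameter_s`, `area_um2`, `duration_s`.
#' @export
ellipsoid_metrics <- function(component, pixel_um, dt_s) {
  w <- component$intensity
  if (any(w < 0) || sum(w) <= 0) stop("component intensities must be positive")
  wm <- function(z) sum(w * z) / sum(w)
  cx <- wm(component$x); cy <- wm(component$y)
  if (nrow(component) == 1L) {
    dx_px <- dy_px <- 1
  } else {
    cov <- matrix(0, 2L, 2L)
    xs <- component$x - cx; ys <- component$y - cy
    cov[1L, 1L] <- sum(w * xs * xs) / sum(w)
    cov[2L, 2L] <- sum(w * ys * ys) / sum(w)
    cov[1L, 2L] <- cov[2L, 1L] <- sum(w * xs * ys) / sum(w)
    ev <- eigen(cov, symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    dx_px <- max(4 * sqrt(ev[1L]), 1)
    dy_px <- max(4 * sqrt(ev[2L]), 1)
  }
  tmin <- min(component$t); tmax <- max(component$t)
  t_diam <- max((tmax - tmin + 1), 1) * dt_s
  dx_um <- dx_px * pixel_um
  dy_um <- dy_px * pixel_um
  # pixel i (0-based) is centred at i * pixel_um, matching the renderer
  list(centroid_x_um = cx * pixel_um,
       centroid_y_um = cy * pixel_um,
       x_diameter_um = dx_um, y_diameter_um = dy_um,
       t_diameter_s = t_diam,
       area_um2 = pi * (dx_um / 2) * (dy_um / 2),
       duration_s = t_diam)
}

#' Classify a transient as sparkle or cell-wide
#'
#' Cell-wide iff the event area is at least `area_threshold_um2`
#' (default 20 um^2, roughly a T cell cross-section); smaller events are
#' localized sparkles.
#'
#' @param area_um2 Event area in um^2 (or a row of a detection table).
#' @param area_threshold_um2 Boundary in um^2.
#' @return `"sparkle"` or `"cell_wide"`.
#' @export
classify_event <- function(area_um2, area_threshold_um2 = 20) {
  if (is.list(area_um2) && !is.null(area_um2$area_um2)) {
    area_um2 <- area_um2$area_um2
  }
  if (area_um2 >= area_threshold_um2) "cell_wide" else "sparkle"
}

#' Summary statistics of detected transients
#'
#' @param events A `"transient_events"` table from [detect_transients()].
#' @param area_breaks,duration_breaks Optional histogram breaks.
#' @return List with `n_events`, `counts_by_class`, `area_hist`,
#'   `duration_hist` (counts + breaks), and per-class summaries of the
#'   SD-normalized integrated intensity.
#' @export
event_statistics <- function(events, area_breaks = NULL, duration_breaks = NULL) {
  if (!nrow(events)) {
    return(list(n_events = 0L,
                counts_by_class = c(sparkle = 0L, cell_wide = 0L),
                area_hist = list(breaks = numeric(0), counts = integer(0)),
                duration_hist = list(breaks = numeric(0), counts = integer(0)),
                norm_intensity = data.frame(klass = character(0), n = integer(0),
                                            mean = numeric(0), sem = numeric(0))))
  }
  counts <- c(sparkle = sum(events$klass == "sparkle"),
              cell_wide = sum(events$klass == "cell_wide"))
  hist_of <- function(x, breaks, default_width) {
    if (is.null(breaks)) {
      breaks <- seq(0, (floor(max(x) / default_width) + 1) * default_width,
                    by = default_width)
    }
    list(breaks = breaks,
         counts = tabulate(findInterval(x, breaks), nbins = length(breaks) - 1L))
  }
  by_class <- do.call(rbind, lapply(split(events, events$klass), function(e) {
    data.frame(klass = e$klass[1L], n = nrow(e),
               mean = mean(e$integrated_norm_intensity),
               sem = if (nrow(e) > 1L)
                 stats::sd(e$integrated_norm_intensity) / sqrt(nrow(e)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  list(n_events = nrow(events), counts_by_class = counts,
       area_hist = hist_of(events$area_um2, area_breaks, 1),
       duration_hist = hist_of(events$duration_s, duration_breaks, 0.5),
       norm_intensity = by_class)
}
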