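#' Construct a single cell track
#'
#' A track is one cell's time series of positions in micrometres, sampled at
#' a (nearly) uniform frame interval, optionally carrying per-frame total
#' green (GCaMP6f) and red (tdTomato) fluorescence intensities.
#'
#' @param cell_id Identifier for the cell (coerced to character).
#' @param t_s Numeric vector of strictly increasing times in seconds.
#' @param pos_um Numeric matrix, one row per frame, 2 or 3 columns
#'   (x, y and optionally z, in micrometres).
#' @param green,red Optional numeric vectors of per-frame total channel
#'   intensities (arbitrary units), same length as `t_s`.
#' @param tol Relative tolerance on frame-interval uniformity (default 1%).
#' @return An object of class `"stopgo_track"`: a list with elements
#'   `cell_id`, `t_s`, `pos_um`, and optionally `green`, `red`.
#' @export
track <- function(cell_id, t_s, pos_um, green = NULL, red = NULL, tol = 0.01) {
  pos_um <- as.matrix(pos_um)
  storage.mode(pos_um) <- "double"
  t_s <- as.numeric(t_s)
  n <- length(t_s)
  if (n < 2L) stop("a track needs at least 2 frames")
  if (nrow(pos_um) != n) stop("t_s and pos_um disagree on frame count")
  if (!ncol(pos_um) %in% c(2L, 3L)) stop("pos_um must have 2 or 3 columns")
  if (any(!is.finite(t_s)) || any(!is.finite(pos_um))) {
    stop("non-finite times or coordinates")
  }
  dt <- diff(t_s)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if ((max(dt) - min(dt)) > tol * stats::median(dt)) {
    stop(sprintf("non-uniform frame interval in track '%s' (spread %.3g s exceeds %g%% of %.3g s)",
                 as.character(cell_id), max(dt) - min(dt), 100 * tol, stats::median(dt)))
  }
  for (nm in c("green", "red")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n) stop(nm, " must have one value per frame")
  }
  structure(list(cell_id = as.character(cell_id), t_s = t_s, pos_um = pos_um,
                 green = green, red = red),
            class = "stopgo_track")
}

#' Collect tracks into a group-labelled track set
#'
#' @param tracks List of [track()] objects sharing dimensionality and frame
#'   interval.
#' @param group Optional character vector of group labels, one per track
#'   (recycled if length 1).
#' @return An object of class `"stopgo_trackset"` with attributes `dim`
#'   (spatial dimensionality) and `dt_s` (median frame interval).
#' @export
track_set <- function(tracks, group = NULL) {
  if (!length(tracks)) stop("empty track set")
  ok <- vapply(tracks, inherits, logical(1), "stopgo_track")
  if (!all(ok)) stop("all elements must be stopgo_track objects")
  dims <- vapply(tracks, function(tr) ncol(tr$pos_um), integer(1))
  if (length(unique(dims)) != 1L) stop("tracks mix 2D and 3D coordinates")
  dts <- vapply(tracks, function(tr) stats::median(diff(tr$t_s)), numeric(1))
  if (is.null(group)) group <- rep("all", length(tracks))
  if (length(group) == 1L) group <- rep(group, length(tracks))
  if (length(group) != length(tracks)) stop("one group label per track required")
  structure(tracks, group = as.character(group), ndim = dims[[1L]],
            dt_s = stats::median(dts), class = "stopgo_trackset")
}

#' @export
print.stopgo_track <- function(x, ...) {
  cat(sprintf("<track '%s': %d frames, %dD, dt = %.3g s%s>\n", x$cell_id,
              length(x$t_s), ncol(x$pos_um), stats::median(diff(x$t_s)),
              if (!is.null(x$green)) ", G/R channels" else ""))
  invisible(x)
}

#' @export
print.stopgo_trackset <- function(x, ...) {
  cat(sprintf("<track set: %d tracks, %dD, dt = %.3g s, groups: %s>\n",
              length(x), attr(x, "ndim"), attr(x, "dt_s"),
              paste(unique(attr(x, "group")), collapse = ", ")))
  invisible(x)
}

#' @export
`[.stopgo_trackset` <- function(x, i) {
  track_set(unclass(x)[i], group = attr(x, "group")[i])
}

#' Flatten a track set to the long data frame / CSV schema
#'
#' Columns: `cell_id, frame, t_s, x_um, y_um[, z_um][, green, red]`.
#' Frames are 0-based.
#'
#' @param x A `stopgo_trackset`.
#' @param ... Unused.
#' @export
as.data.frame.stopgo_trackset <- function(x, ...) {
  out <- lapply(seq_along(x), function(i) {
    tr <- x[[i]]
    df <- data.frame(cell_id = tr$cell_id,
                     frame = seq_along(tr$t_s) - 1L,
                     t_s = tr$t_s,
                     x_um = tr$pos_um[, 1L],
                     y_um = tr$pos_um[, 2L],
                     stringsAsFactors = FALSE)
    if (ncol(tr$pos_um) == 3L) df$z_um <- tr$pos_um[, 3L]
    if (!is.null(tr$green)) df$green <- tr$green
    if (!is.null(tr$red)) df$red <- tr$red
    df
  })
  do.call(rbind, out)
}
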