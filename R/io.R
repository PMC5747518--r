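#' Read a track table CSV into a track set
#'
#' Expected header: `cell_id, frame, t_s, x_um, y_um[, z_um][, green, red]`
#' (plus an optional `group` column). Missing `z_um` gives 2D tracks.
#' Tracks whose sampling is non-uniform beyond 1% are rejected per track
#' with a logged reason; a non-monotone time raises a parse error naming
#' the offending row.
#'
#' @param path CSV file path.
#' @param tol Relative frame-interval tolerance (default 1%).
#' @return A [track_set()].
#' @export
read_tracks <- function(path, tol = 0.01) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("malformed header in ", path, ": need columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  has_z <- "z_um" %in% names(df)
  has_gr <- all(c("green", "red") %in% names(df))
  df <- df[order(match(df$cell_id, unique(df$cell_id)), df$frame), , drop = FALSE]
  rows_by_cell <- split(seq_len(nrow(df)), df$cell_id)
  rows_by_cell <- rows_by_cell[unique(df$cell_id)]
  tracks <- list(); groups <- character(0); dropped <- character(0)
  for (cid in names(rows_by_cell)) {
    rows <- rows_by_cell[[cid]]
    sub <- df[rows, , drop = FALSE]
    bad <- which(diff(sub$t_s) <= 0)
    if (length(bad)) {
      stop(sprintf("parse error in %s: time not increasing for cell '%s' at file row %d",
                   path, cid, rows[bad[1L] + 1L] + 1L))  # +1 for header line
    }
    tr <- tryCatch(
      track(cid, sub$t_s, as.matrix(sub[, c("x_um", "y_um", if (has_z) "z_um")]),
            green = if (has_gr) sub$green else NULL,
            red = if (has_gr) sub$red else NULL, tol = tol),
      error = function(e) e)
    if (inherits(tr, "error")) {
      dropped <- c(dropped, sprintf("%s: %s", cid, conditionMessage(tr)))
      next
    }
    tracks[[length(tracks) + 1L]] <- tr
    groups <- c(groups, if ("group" %in% names(sub)) sub$group[1L] else "all")
  }
  if (length(dropped)) {
    message("dropped ", length(dropped), " track(s):\n  ",
            paste(dropped, collapse = "\n  "))
  }
  if (!length(tracks)) stop("no valid tracks in ", path)
  track_set(tracks, group = groups)
}

#' Write a track set to the track table CSV schema
#'
#' @param ts A [track_set()].
#' @param path Output CSV path.
#' @export
write_tracks <- function(ts, path) {
  df <- as.data.frame(ts)
  df$group <- rep(attr(ts, "group"), vapply(ts, function(tr) length(tr$t_s), integer(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a flat key-value configuration file
#'
#' A minimal YAML-style `key: value` format (flat, one pair per line,
#' `#` comments). Values are parsed as numbers when possible, otherwise
#' kept as strings; this round-trips [pipeline_config()] objects
#' losslessly.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    sprintf("%s: %s", nm, format(config[[nm]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
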